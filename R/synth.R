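#' Ground truth for one synthetic strip image
#'
#' Describes a strip as seen by the onboard camera: a Gaussian test line of
#' known amplitude on a (possibly sloped) background with iid Gaussian pixel
#' noise. Rendering is fully reproducible from `seed`.
#'
#' @param line_amplitude Line peak height above background, intensity units
#'   (>= 0).
#' @param line_center Line center along the flow axis, px (0-based).
#' @param line_sigma Gaussian line width, px (> 0).
#' @param background_level Background intensity at position 0.
#' @param background_slope Background gradient, intensity per px.
#' @param noise_sd Pixel noise standard deviation (>= 0).
#' @param seed Integer seed for the noise.
#' @return An `lfa_strip_truth`.
#' @export
strip_truth <- function(line_amplitude, line_center, line_sigma = 3,
                        background_level = 40, background_slope = 0,
                        noise_sd = 2, seed = 1L) {
  if (line_amplitude < 0) stop("line_amplitude must be >= 0", call. = FALSE)
  if (line_sigma <= 0) stop("line_sigma must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(line_amplitude = line_amplitude, line_center = line_center,
                 line_sigma = line_sigma, background_level = background_level,
                 background_slope = background_slope, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "lfa_strip_truth")
}

#' Render a synthetic strip image
#'
#' Pixels along the flow axis follow
#' `background_level + slope * position + amplitude * exp(-(position - center)^2 / (2 sigma^2))`,
#' constant across the strip width, plus iid Gaussian noise, clipped to the
#' bit depth. Flow is along rows.
#'
#' @param truth An [strip_truth()].
#' @param shape `c(length_along_flow, width)` in pixels; must accommodate
#'   `line_center +/- 4 * line_sigma`.
#' @param bit_depth 8 or 16; sets the clipping range (0..255 or 0..65535).
#' @param search_half_width Search half-width recorded on the returned image.
#' @return List with `image` (an [strip_image()] carrying the expected line
#'   position) and `truth`.
#' @examples
#' st <- render_strip(strip_truth(30, line_center = 60, seed = 7),
#'                    shape = c(120, 30))
#' line_signal(st$image)$signal   # ~30
#' @export
render_strip <- function(truth, shape = c(120L, 30L), bit_depth = 8L,
                         search_half_width = 20L) {
  stopifnot(inherits(truth, "lfa_strip_truth"))
  len <- as.integer(shape[1]); wid <- as.integer(shape[2])
  if (truth$line_center - 4 * truth$line_sigma < 0 ||
      truth$line_center + 4 * truth$line_sigma >= len)
    stop("line (center +/- 4 sigma) falls outside the image", call. = FALSE)
  pos <- seq_len(len) - 1
  clean <- truth$background_level + truth$background_slope * pos +
    truth$line_amplitude *
      exp(-(pos - truth$line_center)^2 / (2 * truth$line_sigma^2))
  px <- matrix(clean, nrow = len, ncol = wid)
  if (truth$noise_sd > 0)
    px <- px + withr::with_seed(truth$seed,
                                matrix(stats::rnorm(len * wid, 0, truth$noise_sd),
                                       nrow = len))
  top <- 2^bit_depth - 1
  px <- pmin(pmax(px, 0), top)
  img <- strip_image(px, flow_axis = "rows",
                     expected_line_position = truth$line_center,
                     search_half_width = search_half_width,
                     max_scale = top)
  list(image = img, truth = truth)
}

#' Write a rendered strip to PNG
#'
#' @param img An [strip_image()] (grayscale).
#' @param path Output `.png`.
#' @export
write_strip_png <- function(img, path) {
  png::writePNG(img$pixels / img$max_scale, path)
  invisible(path)
}

#' Ground truth for a synthetic antibody-pair screen
#'
#' Latent per-antibody affinities generate pair signals through a saturating
#' (Michaelis-Menten-shaped) response; a second antigen gets its own, mostly
#' small, detection-side cross-reactivity coefficients. `planted_pairs`
#' capture/detection pairs are made strongly selective for antigen 1 (high
#' ag1 strength, zero ag2 strength) -- the pairs a screen should recover.
#'
#' @param n_capture,n_detection Panel sizes.
#' @param planted_pairs Number of planted selective top pairs.
#' @param planted_strength Pair binding strength of planted pairs (background
#'   strengths are products of Unif(0.05, 0.8) affinities, so <= 0.64).
#' @param vmax Saturating signal ceiling, intensity units.
#' @param km Half-saturation binding strength.
#' @param blank_level Mean signal of antigen-free matrix.
#' @param blank_sd Blank noise standard deviation.
#' @param replicate_sd Replicate noise standard deviation.
#' @param cross_fraction Fraction of detection antibodies that cross-react
#'   with antigen 2.
#' @param cross_strength ag2 binding strength for cross-reactive detections.
#' @param hook Optional high-dose hook coefficient (0 disables; > 0 bends
#'   the response down at high strength).
#' @param seed Integer seed.
#' @return An `lfa_screen_truth` with affinity vectors and the planted pair
#'   table in `$planted`.
#' @export
screen_truth <- function(n_capture = 16L, n_detection = 16L,
                         planted_pairs = 3L, planted_strength = 5,
                         vmax = 60, km = 1, blank_level = 8, blank_sd = 1.5,
                         replicate_sd = 1.5, cross_fraction = 0.25,
                         cross_strength = 1, hook = 0, seed = 1L) {
  seed <- as.integer(seed)
  withr::with_seed(seed, {
    cap <- stats::runif(n_capture, 0.05, 0.8)
    det <- stats::runif(n_detection, 0.05, 0.8)
    cross <- ifelse(stats::runif(n_detection) < cross_fraction,
                    cross_strength * stats::runif(n_detection, 0.5, 1), 0)
    planted <- data.frame(
      capture = sample.int(n_capture, planted_pairs),
      detection = sample.int(n_detection, planted_pairs))
  })
  names(cap) <- sprintf("Cap%02d", seq_len(n_capture))
  names(det) <- names(cross) <- sprintf("Det%02d", seq_len(n_detection))
  planted$capture <- names(cap)[planted$capture]
  planted$detection <- names(det)[planted$detection]
  structure(list(capture_affinity = cap, detection_affinity = det,
                 cross_reactivity = cross, planted = planted,
                 planted_strength = planted_strength, vmax = vmax, km = km,
                 blank_level = blank_level, blank_sd = blank_sd,
                 replicate_sd = replicate_sd, hook = hook, seed = seed),
            class = "lfa_screen_truth")
}

saturating_response <- function(strength, vmax, km, hook = 0) {
  vmax * strength / (km + strength) / (1 + hook * strength)
}

# pair binding strength per antigen; planted pairs override the product model
pair_strength <- function(truth, antigen) {
  cap <- truth$capture_affinity
  if (antigen == "ag1") {
    s <- outer(cap, truth$detection_affinity)
    for (i in seq_len(nrow(truth$planted)))
      s[truth$planted$capture[i], truth$planted$detection[i]] <-
        truth$planted_strength
  } else {
    s <- outer(rep(1, length(cap)), truth$cross_reactivity)
    dimnames(s) <- list(names(cap), names(truth$cross_reactivity))
    for (i in seq_len(nrow(truth$planted)))
      s[truth$planted$capture[i], truth$planted$detection[i]] <- 0
  }
  s
}

#' Simulate an antibody-pair screen
#'
#' Builds the screen table of a capture x detection x matrix factorial with
#' replicates: the matrix factor must contain a blank level (antigen-free)
#' and may contain `ag1`/`ag2` levels. Replicates of a condition share its
#' latent mean and differ by replicate noise; blanks carry only blank noise
#' around `blank_level`. The output schema is identical to the imaging
#' module's screen table, so downstream analytics cannot tell fixture from
#' real data.
#'
#' @param design An [design_spec()] whose factors include roles
#'   `capture_antibody`, `detection_antibody` and `sample_matrix`; matrix
#'   level names must be among `blank`, `ag1`, `ag2`.
#' @param truth An [screen_truth()]; its capture/detection names must match
#'   the design's levels.
#' @param seed Seed for the noise draw (defaults to `truth$seed`).
#' @return data.frame: `condition_id, capture, detection, matrix, replicate,
#'   signal`.
#' @export
simulate_screen <- function(design, truth, seed = truth$seed) {
  stopifnot(inherits(design, "lfa_design"), inherits(truth, "lfa_screen_truth"))
  roles <- vapply(design$factors, `[[`, "", "role")
  fnames <- vapply(design$factors, `[[`, "", "name")
  need <- c("capture_antibody", "detection_antibody", "sample_matrix")
  if (!all(need %in% roles))
    stop("design needs capture_antibody, detection_antibody and ",
         "sample_matrix factors", call. = FALSE)
  cap_f <- fnames[match("capture_antibody", roles)]
  det_f <- fnames[match("detection_antibody", roles)]
  mat_f <- fnames[match("sample_matrix", roles)]
  conds <- enumerate_conditions(design)
  if (!"blank" %in% conds[[mat_f]])
    stop("the sample_matrix factor needs a 'blank' level", call. = FALSE)

  s1 <- pair_strength(truth, "ag1")
  s2 <- pair_strength(truth, "ag2")
  mean_for <- function(cap, det, mat) {
    if (mat == "blank") return(truth$blank_level)
    s <- if (mat == "ag1") s1[cap, det] else s2[cap, det]
    truth$blank_level + saturating_response(s, truth$vmax, truth$km, truth$hook)
  }
  mu <- mapply(mean_for, conds[[cap_f]], conds[[det_f]], conds[[mat_f]])
  sd <- ifelse(conds[[mat_f]] == "blank", truth$blank_sd, truth$replicate_sd)
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(nrow(conds), 0, sd))
  data.frame(condition_id = conds$condition_id,
             capture = conds[[cap_f]], detection = conds[[det_f]],
             matrix = conds[[mat_f]], replicate = conds$replicate,
             signal = mu + noise, stringsAsFactors = FALSE)
}

#' The standard 16 x 16 x 3 x 2 screening design
#'
#' Convenience constructor for the pair-screening factorial: capture and
#' detection panels crossed with matrices `blank`, `ag1`, `ag2` and
#' technical duplicates (16 x 16 x 3 x 2 = 1536 strips by default).
#'
#' @param n_capture,n_detection Panel sizes.
#' @param replicates Technical replicates.
#' @export
screen_design <- function(n_capture = 16L, n_detection = 16L, replicates = 2L) {
  design_spec(list(
    factor_spec("capture", sprintf("Cap%02d", seq_len(n_capture)),
                role = "capture_antibody"),
    factor_spec("detection", sprintf("Det%02d", seq_len(n_detection)),
                role = "detection_antibody"),
    factor_spec("matrix", c("blank", "ag1", "ag2"), role = "sample_matrix")),
    replicates = replicates)
}
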