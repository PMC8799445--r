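#' Define an experimental factor
#'
#' A factor is one tunable assay variable: a set of capture or detection
#' antibodies, a sample matrix, a reagent concentration series, and so on.
#' Levels may be labels (antibody names, matrix names) or numeric values
#' (concentrations in ug/mL).
#'
#' @param name Factor name; must be unique within a design.
#' @param levels Ordered vector of level labels or numeric values. Numeric
#'   levels must be finite and non-negative.
#' @param role One of `"capture_antibody"`, `"detection_antibody"`,
#'   `"sample_matrix"`, `"concentration"`, `"other"`. Informational; the
#'   enumeration treats all factors alike.
#' @return An object of class `lfa_factor`.
#' @examples
#' factor_spec("capture", paste0("MAb", 1:16), role = "capture_antibody")
#' factor_spec("MAb001", c(0, 15, 30, 60), role = "concentration")
#' @export
factor_spec <- function(name, levels,
                        role = c("other", "capture_antibody", "detection_antibody",
                                 "sample_matrix", "concentration")) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("factor name must be a single non-empty string", call. = FALSE)
  if (length(levels) == 0L)
    stop("factor '", name, "' has no levels", call. = FALSE)
  if (anyDuplicated(levels))
    stop("factor '", name, "' has duplicate levels", call. = FALSE)
  if (is.numeric(levels) && (any(!is.finite(levels)) || any(levels < 0)))
    stop("numeric levels of factor '", name, "' must be finite and >= 0",
         call. = FALSE)
  structure(list(name = name, role = role, levels = levels),
            class = "lfa_factor")
}

#' Define a factorial design
#'
#' @param factors List of [factor_spec()] objects (declaration order fixes the
#'   enumeration order).
#' @param replicates Technical replicates per unique factor-level assignment
#'   (integer >= 1).
#' @param exclusions List of exclusion predicates built with
#'   [exclude_levels()] or [exclude_all_zero()].
#' @param controls Optional named list of control assignments (each a named
#'   list factor -> level); informational, carried through to outputs.
#' @return An object of class `lfa_design`.
#' @examples
#' design_spec(
#'   list(factor_spec("capture", c("A", "B")), factor_spec("conc", c(0, 10))),
#'   replicates = 2
#' )
#' @export
design_spec <- function(factors, replicates = 1L, exclusions = list(),
                        controls = list()) {
  if (inherits(factors, "lfa_factor")) factors <- list(factors)
  if (!length(factors) || !all(vapply(factors, inherits, TRUE, "lfa_factor")))
    stop("'factors' must be a non-empty list of factor_spec objects", call. = FALSE)
  nms <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("factor names must be unique", call. = FALSE)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("replicates must be an integer >= 1", call. = FALSE)
  if (inherits(exclusions, "lfa_exclusion")) exclusions <- list(exclusions)
  ok <- vapply(exclusions, inherits, TRUE, "lfa_exclusion")
  if (!all(ok)) stop("exclusions must be built with exclude_levels()/exclude_all_zero()",
                     call. = FALSE)
  for (ex in exclusions) {
    bad <- setdiff(exclusion_factors(ex), nms)
    if (length(bad))
      stop("exclusion references unknown factor(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(list(factors = factors, replicates = replicates,
                 exclusions = exclusions, controls = controls),
            class = "lfa_design")
}

#' @export
print.lfa_design <- function(x, ...) {
  nlev <- vapply(x$factors, function(f) length(f$levels), 0L)
  cat("LFA factorial design:", length(x$factors), "factors,",
      prod(nlev), "raw assignments x", x$replicates, "replicate(s)\n")
  for (f in x$factors)
    cat("  ", f$name, " [", f$role, "]: ",
        paste(utils::head(f$levels, 6), collapse = ", "),
        if (length(f$levels) > 6) ", ..." else "", "\n", sep = "")
  if (length(x$exclusions)) cat("  exclusions:", length(x$exclusions), "\n")
  invisible(x)
}

#' Exclusion: conjunction of per-factor level tests
#'
#' A condition is excluded when, for *every* named factor, its level is in the
#' given set. `exclude_levels(capture = "MAb001", matrix = "blank")` removes
#' conditions that have both.
#'
#' @param ... Named arguments; each name a factor, each value a vector of
#'   levels to match.
#' @return An `lfa_exclusion`.
#' @export
exclude_levels <- function(...) {
  tests <- list(...)
  if (!length(tests) || is.null(names(tests)) || any(!nzchar(names(tests))))
    stop("exclude_levels() needs named factor = levels arguments", call. = FALSE)
  structure(list(type = "levels", tests = tests), class = "lfa_exclusion")
}

#' Exclusion: all named numeric factors are zero
#'
#' Removes assignments where every listed concentration factor is 0 --
#' e.g. the all-zero antibody mixture of a 4x4x4 concentration grid,
#' leaving 63 of the 64 combinations.
#'
#' @param factors Character vector of (numeric-level) factor names.
#' @return An `lfa_exclusion`.
#' @export
exclude_all_zero <- function(factors) {
  stopifnot(is.character(factors), length(factors) >= 1L)
  structure(list(type = "all_zero", factors = factors), class = "lfa_exclusion")
}

exclusion_factors <- function(ex) {
  switch(ex$type, levels = names(ex$tests), all_zero = ex$factors)
}

# logical vector: TRUE where the assignment row is excluded
exclusion_mask <- function(grid, exclusions) {
  if (!length(exclusions)) return(rep(FALSE, nrow(grid)))
  masks <- lapply(exclusions, function(ex) {
    if (ex$type == "levels") {
      Reduce(`&`, lapply(names(ex$tests),
                         function(f) grid[[f]] %in% ex$tests[[f]]))
    } else {
      Reduce(`&`, lapply(ex$factors,
                         function(f) as.numeric(grid[[f]]) == 0))
    }
  })
  Reduce(`|`, masks)
}

format_level <- function(x) {
  if (is.numeric(x)) vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE), "")
  else as.character(x)
}

#' Enumerate all conditions of a design
#'
#' Expands the full Cartesian product of factor levels, drops excluded
#' assignments, and repeats each surviving assignment once per replicate.
#' Order is deterministic: lexicographic by factor declaration order (first
#' factor varies slowest), then level order, then replicate index, so re-runs
#' produce identical tables and condition ids.
#'
#' @param design An [design_spec()] object.
#' @return A data.frame with columns `condition_id`, one column per factor,
#'   and `replicate`. The readable id has the form
#'   `"capture=MAb001;detection=MAb002;rep=1"`.
#' @examples
#' d <- design_spec(list(factor_spec("a", 1:2), factor_spec("b", c("x", "y"))),
#'                  replicates = 2)
#' enumerate_conditions(d)
#' @export
enumerate_conditions <- function(design) {
  stopifnot(inherits(design, "lfa_design"))
  lv <- lapply(design$factors, `[[`, "levels")
  names(lv) <- vapply(design$factors, `[[`, "", "name")
  # expand.grid varies the first input fastest; reverse twice so the first
  # declared factor varies slowest (lexicographic by declaration order)
  grid <- rev(expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE))
  keep <- !exclusion_mask(grid, design$exclusions)
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L)
    stop("design eliminates all conditions", call. = FALSE)
  r <- design$replicates
  out <- grid[rep(seq_len(nrow(grid)), each = r), , drop = FALSE]
  out$replicate <- rep(seq_len(r), times = nrow(grid))
  rownames(out) <- NULL
  id_parts <- mapply(function(col, nm) paste0(nm, "=", format_level(col)),
                     out[names(lv)], names(lv), SIMPLIFY = FALSE)
  out$condition_id <- paste0(do.call(paste, c(id_parts, sep = ";")),
                             ";rep=", out$replicate)
  out[, c("condition_id", names(lv), "replicate")]
}

#' Describe the robot deck
#'
#' @param holders data.frame with columns `holder_id`, `strip_capacity`, and
#'   optionally `type` (`"strips"`, capacity <= 16, or `"cassettes"`,
#'   capacity <= 96; default `"strips"`).
#' @param wells_per_strip Wells addressable on each strip (sample port,
#'   conjugate well, ...).
#' @return An `lfa_deck` with `run_capacity = sum(strip_capacity)`.
#' @examples
#' deck_layout(data.frame(holder_id = c("H1", "H2"), strip_capacity = 16))
#' @export
deck_layout <- function(holders, wells_per_strip = 2L) {
  holders <- as.data.frame(holders, stringsAsFactors = FALSE)
  stopifnot(all(c("holder_id", "strip_capacity") %in% names(holders)))
  if (is.null(holders$type)) holders$type <- "strips"
  if (anyDuplicated(holders$holder_id))
    stop("holder ids must be unique", call. = FALSE)
  holders$strip_capacity <- as.integer(holders$strip_capacity)
  cap_lim <- ifelse(holders$type == "cassettes", 96L, 16L)
  if (any(holders$strip_capacity < 1L | holders$strip_capacity > cap_lim))
    stop("holder capacity out of range (<=16 for strip holders, <=96 for cassette holders)",
         call. = FALSE)
  wells_per_strip <- as.integer(wells_per_strip)
  stopifnot(wells_per_strip >= 1L)
  structure(list(holders = holders, wells_per_strip = wells_per_strip,
                 run_capacity = sum(holders$strip_capacity)),
            class = "lfa_deck")
}

#' @export
print.lfa_deck <- function(x, ...) {
  cat("LFA deck:", nrow(x$holders), "holder(s),",
      x$run_capacity, "strips per run,",
      x$wells_per_strip, "well(s) per strip\n")
  invisible(x)
}

#' Partition conditions into robot runs
#'
#' Fills runs strictly in enumeration order: the first `run_capacity`
#' conditions form run 1, and so on, giving exactly
#' `ceiling(n / run_capacity)` runs. Within a run, slots are filled holder by
#' holder in declaration order. Because enumeration places replicates of the
#' same assignment next to each other, replicates land in the same run except
#' across a run boundary (best-effort, not guaranteed).
#'
#' @param conditions Output of [enumerate_conditions()].
#' @param deck An [deck_layout()] object.
#' @return `conditions` with added `run_index`, `holder_id`, `slot_index`
#'   columns (slots are 1-based within each holder).
#' @export
split_into_runs <- function(conditions, deck) {
  stopifnot(inherits(deck, "lfa_deck"), is.data.frame(conditions))
  cap <- deck$run_capacity
  if (cap < 1L) stop("run capacity must be >= 1", call. = FALSE)
  n <- nrow(conditions)
  run_index <- if (n) rep(seq_len(ceiling(n / cap)), each = cap)[seq_len(n)] else integer()
  hid <- rep(deck$holders$holder_id, deck$holders$strip_capacity)
  sidx <- sequence(deck$holders$strip_capacity)
  slot_in_run <- if (n) sequence(tabulate(run_index)) else integer()
  conditions$run_index <- run_index
  conditions$holder_id <- hid[slot_in_run]
  conditions$slot_index <- sidx[slot_in_run]
  conditions
}

#' Optionally shuffle run order (seeded, opt-in)
#'
#' Randomised run order is off by default; pass a seed to permute the
#' condition order reproducibly before [split_into_runs()].
#'
#' @param conditions Condition table.
#' @param seed Integer seed.
#' @return Permuted condition table.
#' @export
shuffle_conditions <- function(conditions, seed) {
  stopifnot(is.data.frame(conditions))
  withr::with_seed(as.integer(seed), {
    conditions[sample.int(nrow(conditions)), , drop = FALSE]
  })
}
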