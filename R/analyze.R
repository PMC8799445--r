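check_screen_table <- function(table) {
  need <- c("capture", "detection", "matrix", "replicate", "signal")
  if (!all(need %in% names(table)))
    stop("screen table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(table$signal)))
    stop("screen table signals must be finite", call. = FALSE)
  key <- paste(table$capture, table$detection, table$matrix, table$replicate)
  if (anyDuplicated(key))
    stop("duplicate (capture, detection, matrix, replicate) rows", call. = FALSE)
  invisible(table)
}

#' Read / write screen tables
#'
#' The flat CSV schema shared by the imaging and synthetic modules:
#' `capture, detection, matrix, replicate, signal` (plus any id columns).
#' @param path CSV file.
#' @export
read_screen_csv <- function(path) {
  check_screen_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_screen_csv
#' @param table Screen table.
#' @export
write_screen_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Blank-subtract a screen table
#'
#' For every (capture, detection) pair, the mean signal over replicates in
#' each matrix minus that pair's own blank mean. Blanks therefore map to
#' exactly zero. Pairs without any blank replicate are an error (listed in
#' the message); missing replicates elsewhere are averaged over what is
#' present, with `n_replicates` reported.
#'
#' @param table Screen table (`capture, detection, matrix, replicate,
#'   signal`).
#' @param blank_matrix Level of `matrix` that holds antigen-free samples.
#' @return data.frame: `capture, detection, matrix, mean_signal,
#'   n_replicates, blank_mean, signal_bsub`.
#' @examples
#' tb <- data.frame(capture = "A", detection = "B",
#'                  matrix = rep(c("ag1", "blank"), each = 2),
#'                  replicate = c(1, 2, 1, 2), signal = c(10, 12, 2, 2))
#' blank_subtract(tb)   # ag1 row: 11 - 2 = 9
#' @export
blank_subtract <- function(table, blank_matrix = "blank") {
  check_screen_table(table)
  agg <- stats::aggregate(signal ~ capture + detection + matrix, data = table,
                          FUN = mean)
  names(agg)[names(agg) == "signal"] <- "mean_signal"
  n <- stats::aggregate(signal ~ capture + detection + matrix, data = table,
                        FUN = length)
  agg$n_replicates <- n$signal
  bl <- agg[agg$matrix == blank_matrix, c("capture", "detection", "mean_signal")]
  names(bl)[3] <- "blank_mean"
  out <- merge(agg, bl, by = c("capture", "detection"), all.x = TRUE,
               sort = FALSE)
  if (anyNA(out$blank_mean)) {
    miss <- unique(paste0(out$capture[is.na(out$blank_mean)], "/",
                          out$detection[is.na(out$blank_mean)]))
    stop("no blank replicates for pair(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out$signal_bsub <- out$mean_signal - out$blank_mean
  out <- out[order(out$capture, out$detection, out$matrix), ]
  rownames(out) <- NULL
  out
}

#' Capture x detection heatmap of replicate-averaged signals
#'
#' Cell (i, j) is the mean signal over replicates of capture i with
#' detection j in the requested matrix (optionally blank-subtracted).
#' Missing cells stay `NA` and are flagged, never imputed.
#'
#' @param table Screen table.
#' @param antigen_matrix Which `matrix` level to map.
#' @param blank_subtracted If `TRUE`, subtract each pair's blank mean first.
#' @param blank_matrix Blank level name.
#' @return Numeric matrix (captures x detections) with attribute
#'   `"missing_cells"` (count of NA cells).
#' @export
pair_heatmap <- function(table, antigen_matrix, blank_subtracted = FALSE,
                         blank_matrix = "blank") {
  check_screen_table(table)
  caps <- sort(unique(table$capture))
  dets <- sort(unique(table$detection))
  if (blank_subtracted) {
    bs <- blank_subtract(table, blank_matrix)
    sub <- bs[bs$matrix == antigen_matrix, ]
    val <- sub$signal_bsub
  } else {
    sub <- table[table$matrix == antigen_matrix, ]
    sub <- stats::aggregate(signal ~ capture + detection, data = sub,
                            FUN = mean)
    val <- sub$signal
  }
  m <- matrix(NA_real_, length(caps), length(dets),
              dimnames = list(caps, dets))
  m[cbind(match(sub$capture, caps), match(sub$detection, dets))] <- val
  attr(m, "missing_cells") <- sum(is.na(m))
  m
}

#' Per-pair screening summary with S/N and S-N metrics
#'
#' For each (capture, detection) pair and each antigen matrix:
#' `s_minus_n = mean_signal - blank_mean` (exact) and
#' `s_over_n = mean_signal / blank_mean`, the pair's own blank mean serving
#' as N (set `global_blank = TRUE` to use the plate-wide blank mean
#' instead). `s_over_n` is `NA` when the blank mean is not positive.
#'
#' @param table Screen table.
#' @param blank_matrix Blank level name.
#' @param global_blank Use one plate-wide blank mean as N for every pair.
#' @return data.frame, one row per pair per non-blank matrix: `capture,
#'   detection, matrix, mean_signal, n_replicates, blank_mean, s_minus_n,
#'   s_over_n`.
#' @export
pair_summary <- function(table, blank_matrix = "blank", global_blank = FALSE) {
  bs <- blank_subtract(table, blank_matrix)
  out <- bs[bs$matrix != blank_matrix, ]
  if (global_blank)
    out$blank_mean <- mean(table$signal[table$matrix == blank_matrix])
  out$s_minus_n <- out$mean_signal - out$blank_mean
  out$s_over_n <- ifelse(out$blank_mean > 0,
                         out$mean_signal / out$blank_mean, NA_real_)
  out$signal_bsub <- NULL
  rownames(out) <- NULL
  out
}

#' Rank antibody pairs by target signal, filtering cross-reactive ones
#'
#' Pairs are sorted by descending blank-subtracted signal with the target
#' antigen; pairs whose blank-subtracted signal with the off-target antigen
#' exceeds `ag2_threshold` are filtered out of the ranking (they remain in
#' the scatter table). The default threshold is 3x the blank replicate
#' standard deviation estimated from the table. The scatter table
#' (x = off-target, y = target) mirrors the screen's selectivity plot.
#'
#' @param table Screen table covering both antigen matrices.
#' @param ag1 Target antigen matrix level.
#' @param ag2 Off-target antigen matrix level.
#' @param ag2_threshold Cross-reactivity cut-off on the ag2 blank-subtracted
#'   signal; `NULL` for the 3-sigma default.
#' @param blank_matrix Blank level name.
#' @return An `lfa_rank`: `ranking` (passing pairs, best first), `scatter`
#'   (all pairs with `ag1_signal`, `ag2_signal`, `selected`), `threshold`.
#' @export
cross_reactivity_rank <- function(table, ag1 = "ag1", ag2 = "ag2",
                                  ag2_threshold = NULL,
                                  blank_matrix = "blank") {
  bs <- blank_subtract(table, blank_matrix)
  if (!all(c(ag1, ag2) %in% bs$matrix))
    stop("table must contain both antigen matrices '", ag1, "' and '", ag2,
         "'", call. = FALSE)
  if (is.null(ag2_threshold)) {
    blanks <- table$signal[table$matrix == blank_matrix]
    ag2_threshold <- 3 * stats::sd(blanks)
  }
  a1 <- bs[bs$matrix == ag1, c("capture", "detection", "signal_bsub")]
  a2 <- bs[bs$matrix == ag2, c("capture", "detection", "signal_bsub")]
  names(a1)[3] <- "ag1_signal"
  names(a2)[3] <- "ag2_signal"
  sc <- merge(a1, a2, by = c("capture", "detection"), sort = FALSE)
  sc$selected <- sc$ag2_signal <= ag2_threshold
  sc <- sc[order(-sc$ag1_signal, sc$capture, sc$detection), ]
  rownames(sc) <- NULL
  ranking <- sc[sc$selected, c("capture", "detection", "ag1_signal",
                               "ag2_signal")]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, scatter = sc, threshold = ag2_threshold),
            class = "lfa_rank")
}

#' @export
print.lfa_rank <- function(x, ...) {
  cat("Cross-reactivity ranking:", nrow(x$ranking), "of", nrow(x$scatter),
      "pairs pass ag2 threshold", format(x$threshold, digits = 3), "\n")
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' Pearson correlation between two quantification methods
#'
#' Standard product-moment correlation with the two-sided p-value from the
#' t transform, for comparing paired signals from two readouts of the same
#' strips (robot camera vs. bench reader, LFA vs. plate assay, ...).
#'
#' @param x,y Paired finite signal vectors, length >= 3.
#' @return List: `r`, `p`, `n`.
#' @examples
#' method_correlation(1:10, 2 * (1:10) + 1)$r  # 1
#' @export
method_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("signals must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the signal vectors", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
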