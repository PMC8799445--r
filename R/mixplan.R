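#' Stock solution table
#'
#' Stocks are single-component solutions identified by `stock_id`, carrying
#' one `component` at `concentration` ug/mL with `volume` uL available.
#' The diluent is a distinguished stock whose concentration is 0 for every
#' component (see [diluent_stock()]).
#'
#' @param stock_id,component,concentration,volume Vectors of equal length
#'   (recycled by `data.frame`).
#' @return data.frame of class `lfa_stocks`.
#' @examples
#' stock_table(c("A240", "B240"), c("A", "B"), 240, 1000)
#' @export
stock_table <- function(stock_id, component, concentration, volume = Inf) {
  df <- data.frame(stock_id = as.character(stock_id),
                   component = as.character(component),
                   concentration = as.numeric(concentration),
                   volume = as.numeric(volume),
                   stringsAsFactors = FALSE)
  if (any(df$concentration < 0) || any(!is.finite(df$concentration)))
    stop("stock concentrations must be finite and >= 0", call. = FALSE)
  if (any(df$volume < 0)) stop("stock volumes must be >= 0", call. = FALSE)
  class(df) <- c("lfa_stocks", "data.frame")
  df
}

#' The distinguished diluent stock
#'
#' @param stock_id Label used for the buffer/diluent in recipes and worklists.
#' @param volume Available volume, uL.
#' @export
diluent_stock <- function(stock_id = "buffer", volume = Inf) {
  stock_table(stock_id, component = ".diluent", concentration = 0,
              volume = volume)
}

#' Read stocks from CSV
#'
#' Expected columns: `stock_id, component, concentration, volume`
#' (concentration ug/mL, volume uL; empty volume means unlimited).
#' @param path CSV file.
#' @export
read_stocks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stock_id", "component", "concentration")
  if (!all(need %in% names(df)))
    stop("stocks CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(df$volume)) df$volume <- Inf
  df$volume[is.na(df$volume)] <- Inf
  stock_table(df$stock_id, df$component, df$concentration, df$volume)
}

new_recipe <- function(target_id, target_concentrations, final_volume,
                       transfers, diluent_volume) {
  structure(list(target_id = target_id,
                 target_concentrations = target_concentrations,
                 final_volume = final_volume,
                 transfers = transfers,
                 diluent_volume = diluent_volume),
            class = "lfa_recipe")
}

#' @export
print.lfa_recipe <- function(x, ...) {
  cat("MixRecipe '", x$target_id, "': ", x$final_volume, " uL\n", sep = "")
  for (i in seq_len(nrow(x$transfers)))
    cat(sprintf("  %-12s %8.4g uL  (%s)\n", x$transfers$stock_id[i],
                x$transfers$volume[i], x$transfers$component[i]))
  cat(sprintf("  %-12s %8.4g uL\n", "diluent", x$diluent_volume))
  invisible(x)
}

#' Plan one working mixture from stocks
#'
#' Solves the single-component mass balance
#' `V_c = target_c * final_volume / stock_conc_c` for every component, with
#' the remainder made up by diluent, so that
#' `sum(conc_stock * V_stock) == target_conc * final_volume` exactly for each
#' component and volumes sum exactly to `final_volume`.
#'
#' @param targets Named numeric vector, component -> target concentration
#'   (ug/mL). Zero targets draw zero volume.
#' @param stocks An [stock_table()]; every non-zero target component must
#'   appear in exactly one single-component stock.
#' @param final_volume Total mixture volume, uL (> 0).
#' @param target_id Identifier for the recipe.
#' @return An `lfa_recipe`.
#' @examples
#' st <- stock_table("A120", "A", 120)
#' plan_mixture(c(A = 60), st, 100)   # 50 uL stock + 50 uL diluent
#' @export
plan_mixture <- function(targets, stocks, final_volume, target_id = "mix") {
  stopifnot(is.numeric(targets), !is.null(names(targets)),
            inherits(stocks, "data.frame"))
  if (!is.numeric(final_volume) || final_volume <= 0)
    stop("final_volume must be > 0", call. = FALSE)
  if (any(targets < 0) || any(!is.finite(targets)))
    stop("target concentrations must be finite and >= 0", call. = FALSE)

  comps <- names(targets)
  vol <- numeric(length(comps))
  src <- rep(NA_character_, length(comps))
  for (i in seq_along(comps)) {
    rows <- stocks[stocks$component == comps[i] & stocks$component != ".diluent", ,
                   drop = FALSE]
    if (nrow(rows) == 0L) {
      if (targets[i] == 0) next
      stop("no stock carries component '", comps[i], "'", call. = FALSE)
    }
    if (nrow(rows) > 1L)
      stop("component '", comps[i], "' is in more than one stock; ",
           "ambiguous source", call. = FALSE)
    multi <- stocks$stock_id == rows$stock_id[1] & stocks$component != comps[i]
    if (any(multi))
      stop("stock '", rows$stock_id[1], "' is multi-component; not supported",
           call. = FALSE)
    src[i] <- rows$stock_id[1]
    if (targets[i] == 0) { vol[i] <- 0; next }
    if (targets[i] > rows$concentration[1])
      stop("infeasible: over-concentrated (component '", comps[i], "' target ",
           targets[i], " > stock ", rows$concentration[1], " ug/mL)",
           call. = FALSE)
    vol[i] <- targets[i] * final_volume / rows$concentration[1]
  }
  total <- sum(vol)
  if (total > final_volume * (1 + 1e-12))
    stop("infeasible: volume overflow (stock volumes ",
         format(total), " uL exceed final volume ", final_volume, " uL)",
         call. = FALSE)
  short <- which(!is.na(src) & vol > stocks$volume[match(src, stocks$stock_id)])
  if (length(short))
    stop("insufficient stock: ",
         paste(src[short], collapse = ", "), call. = FALSE)
  keep <- !is.na(src)
  transfers <- data.frame(stock_id = src[keep], component = comps[keep],
                          volume = vol[keep], stringsAsFactors = FALSE)
  new_recipe(target_id, targets, final_volume, transfers,
             diluent_volume = final_volume - total)
}

#' Concentrations actually achieved by a recipe
#'
#' Recomputes each component concentration from the emitted transfer volumes
#' (`sum(conc * V) / final_volume`); used to verify mass balance.
#'
#' @param recipe An `lfa_recipe`.
#' @param stocks The stock table the recipe was planned from.
#' @return Named numeric vector on the same components as the targets.
#' @export
achieved_concentrations <- function(recipe, stocks) {
  out <- recipe$target_concentrations
  out[] <- 0
  for (i in seq_len(nrow(recipe$transfers))) {
    tr <- recipe$transfers[i, ]
    conc <- stocks$concentration[stocks$stock_id == tr$stock_id &
                                   stocks$component == tr$component]
    out[tr$component] <- out[tr$component] +
      conc * tr$volume / recipe$final_volume
  }
  out
}

#' Round recipe volumes to the instrument's pipetting resolution
#'
#' Recipes carry exact volumes; this quantization step rounds each transfer
#' to a multiple of `resolution` (default 0.1 uL), recomputes the diluent so
#' volumes still sum to `final_volume`, and reports the resulting relative
#' concentration error per component in the `"quantization_error"` attribute.
#'
#' @param recipe An `lfa_recipe`.
#' @param stocks Stock table (for the error report).
#' @param resolution Pipetting resolution, uL.
#' @return Quantized `lfa_recipe`.
#' @export
quantize_recipe <- function(recipe, stocks, resolution = 0.1) {
  stopifnot(resolution > 0)
  q <- recipe
  q$transfers$volume <- round(recipe$transfers$volume / resolution) * resolution
  q$diluent_volume <- recipe$final_volume - sum(q$transfers$volume)
  if (q$diluent_volume < 0)
    stop("quantized volumes exceed final volume; use a finer resolution",
         call. = FALSE)
  ach <- achieved_concentrations(q, stocks)
  tgt <- recipe$target_concentrations
  rel <- ifelse(tgt > 0, (ach - tgt) / tgt, ach)
  attr(q, "quantization_error") <-
    data.frame(component = names(tgt), target = as.numeric(tgt),
               achieved = as.numeric(ach), rel_error = as.numeric(rel))
  q
}

#' Plan a serial dilution series
#'
#' Step `k` holds `top_conc / fold^k` (k = 1..n_steps): each step receives
#' `carryover` uL of the previous solution (step 1 from the `top` source)
#' topped up with diluent to `volume_per_step` uL, so the dilution at each
#' step is `carryover / volume_per_step`. `fold` and `carryover` are linked
#' by `carryover = volume_per_step / fold`; the default derives `carryover`,
#' and an explicit inconsistent pair is an error.
#'
#' @param top_conc Concentration of the source solution, ug/mL.
#' @param fold Dilution factor per step (> 1).
#' @param n_steps Number of steps (>= 1).
#' @param volume_per_step Final volume at every step, uL.
#' @param carryover Volume transferred between consecutive steps, uL.
#' @param component Component label carried through the recipes.
#' @param top_id Stock id of the starting solution.
#' @return List of `lfa_recipe` (one per step, ids `dil_1`, `dil_2`, ...),
#'   with the step concentrations in attribute `"concentrations"`.
#' @examples
#' d <- plan_serial_dilution(60, fold = 2, n_steps = 3, volume_per_step = 100)
#' attr(d, "concentrations")  # 30 15 7.5
#' @export
plan_serial_dilution <- function(top_conc, fold, n_steps, volume_per_step = 100,
                                 carryover = volume_per_step / fold,
                                 component = "analyte", top_id = "top") {
  if (!(fold > 1)) stop("fold must be > 1", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
  if (carryover >= volume_per_step)
    stop("carryover must be smaller than volume_per_step", call. = FALSE)
  if (carryover <= 0) stop("carryover must be > 0", call. = FALSE)
  if (abs(carryover * fold - volume_per_step) > 1e-9 * volume_per_step)
    stop("carryover (", carryover, " uL) inconsistent with fold ", fold,
         " at ", volume_per_step, " uL per step", call. = FALSE)
  conc <- top_conc / fold^seq_len(n_steps)
  ids <- paste0("dil_", seq_len(n_steps))
  srcs <- c(top_id, ids[-n_steps])
  out <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    tgt <- stats::setNames(conc[k], component)
    out[[k]] <- new_recipe(
      ids[k], tgt, volume_per_step,
      transfers = data.frame(stock_id = srcs[k], component = component,
                             volume = carryover, stringsAsFactors = FALSE),
      diluent_volume = volume_per_step - carryover)
  }
  attr(out, "concentrations") <- conc
  out
}

#' Write recipes as a flat CSV
#'
#' One row per transfer plus one diluent row per recipe; consumed by the
#' scheduling module or external tools.
#' @param recipes List of `lfa_recipe`.
#' @param path Output CSV.
#' @export
write_recipes_csv <- function(recipes, path) {
  if (inherits(recipes, "lfa_recipe")) recipes <- list(recipes)
  rows <- lapply(recipes, function(r) {
    tr <- r$transfers
    rbind(data.frame(target_id = r$target_id, stock_id = tr$stock_id,
                     component = tr$component, volume = tr$volume,
                     final_volume = r$final_volume, stringsAsFactors = FALSE),
          data.frame(target_id = r$target_id, stock_id = "buffer",
                     component = ".diluent", volume = r$diluent_volume,
                     final_volume = r$final_volume, stringsAsFactors = FALSE))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
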