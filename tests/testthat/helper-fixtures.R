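# shared fixtures and independent oracles

# brute-force condition count: nested loops, no vectorised enumeration
brute_force_count <- function(design) {
  lv <- lapply(design$factors, `[[`, "levels")
  names(lv) <- vapply(design$factors, `[[`, "", "name")
  idx <- rep(1L, length(lv))
  total <- 0L
  repeat {
    assign_row <- as.data.frame(
      Map(function(l, i) l[i], lv, as.list(idx)), stringsAsFactors = FALSE)
    names(assign_row) <- names(lv)
    excluded <- FALSE
    for (ex in design$exclusions) {
      hit <- if (ex$type == "levels") {
        all(vapply(names(ex$tests),
                   function(f) assign_row[[f]] %in% ex$tests[[f]], TRUE))
      } else {
        all(vapply(ex$factors, function(f) as.numeric(assign_row[[f]]) == 0,
                   TRUE))
      }
      if (hit) { excluded <- TRUE; break }
    }
    if (!excluded) total <- total + 1L
    k <- length(idx)
    while (k >= 1L) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= length(lv[[k]])) break
      idx[k] <- 1L
      k <- k - 1L
    }
    if (k < 1L) break
  }
  total * design$replicates
}

# mass-balance arithmetic straight from a recipe's transfers
oracle_achieved <- function(recipe, stocks) {
  out <- recipe$target_concentrations
  for (comp in names(out)) {
    tot <- 0
    for (i in seq_len(nrow(recipe$transfers))) {
      conc <- stocks$concentration[stocks$stock_id == recipe$transfers$stock_id[i] &
                                     stocks$component == recipe$transfers$component[i]]
      if (recipe$transfers$component[i] == comp)
        tot <- tot + conc * recipe$transfers$volume[i]
    }
    out[comp] <- tot / recipe$final_volume
  }
  out
}

std_deck <- function(n_holders = 6L) {
  deck_layout(data.frame(holder_id = sprintf("H%d", seq_len(n_holders)),
                         strip_capacity = 16L))
}

std_protocol <- function(target_time = 1800, tol = 60, sample_delay = 120) {
  assay_protocol(
    protocol_step("dispense_reagent", reagent = "conjugate", volume = 10,
                  destination = "conjugate_well", duration = 30,
                  liquid_class = "HighVis"),
    protocol_step("dispense_sample", reagent = "sample", volume = 50,
                  destination = "sample_port", min_delay = sample_delay,
                  duration = 30),
    protocol_step("image", target_time = target_time, duration = 10),
    imaging_tolerance = tol)
}

std_reagents <- function() list(conjugate = "conj_stock", sample = "sample_stock")

# n-strip single-factor run, already slotted
strip_run <- function(n, deck = std_deck()) {
  d <- design_spec(list(factor_spec("strip", sprintf("S%03d", seq_len(n)))))
  split_into_runs(enumerate_conditions(d), deck)
}

# per-strip bijection: every (condition, protocol step) exactly once, in order
expect_worklist_bijection <- function(worklist, protocol, conditions) {
  ev <- worklist$events[worklist$events$condition_id != "", ]
  actions <- vapply(protocol$steps, `[[`, "", "action")
  for (cid in conditions$condition_id) {
    rows <- ev[ev$condition_id == cid, ]
    rows <- rows[order(rows$scheduled_start_s), ]
    expect_equal(nrow(rows), length(actions), info = cid)
    expect_equal(rows$action, actions, info = cid)
  }
  expect_setequal(unique(ev$condition_id), conditions$condition_id)
}
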