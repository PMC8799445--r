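#' Define one step of an assay protocol
#'
#' Liquid steps (`dispense_reagent`, `dispense_sample`) move `volume` uL of a
#' reagent to a well on each strip. `image` steps photograph each strip at
#' `target_time` seconds after that strip's sample dispense (e.g. 1800 s or
#' 2100 s for 30/35-min reads), within the protocol's imaging tolerance.
#' `min_delay` is the minimum time between the start of the previous step and
#' the start of this one, per strip. `duration` is the gantry time one
#' channel-batch of this step occupies.
#'
#' @param action `"dispense_reagent"`, `"dispense_sample"` or `"image"`.
#' @param reagent Reagent key (character), or a function of the condition row
#'   returning a key, resolved against the `reagents` argument of
#'   [expand_protocol()]. Ignored for image steps.
#' @param volume Dispensed volume, uL.
#' @param destination Well role on the strip (`"sample_port"`,
#'   `"conjugate_well"`, ...).
#' @param min_delay Seconds after the previous step's start (>= 0).
#' @param target_time Seconds after the sample dispense at which imaging
#'   should occur; required for image steps.
#' @param liquid_class Opaque instrument liquid-class label.
#' @param duration Seconds of gantry time per batch.
#' @return An `lfa_step`.
#' @export
protocol_step <- function(action = c("dispense_reagent", "dispense_sample", "image"),
                          reagent = NULL, volume = 0, destination = "sample_port",
                          min_delay = 0, target_time = NULL,
                          liquid_class = "StandardVolume", duration = 10) {
  action <- match.arg(action)
  if (action == "image" && is.null(target_time))
    stop("image steps need target_time (seconds after sample dispense)",
         call. = FALSE)
  if (volume < 0 || min_delay < 0 || duration <= 0)
    stop("volume and min_delay must be >= 0, duration > 0", call. = FALSE)
  structure(list(action = action, reagent = reagent, volume = volume,
                 destination = destination, min_delay = min_delay,
                 target_time = if (is.null(target_time)) NA_real_ else target_time,
                 liquid_class = liquid_class, duration = duration),
            class = "lfa_step")
}

#' Assemble an assay protocol
#'
#' @param ... [protocol_step()] objects in execution order (or a single list
#'   of them). If any image step is present there must be exactly one
#'   `dispense_sample` step, since imaging times are defined relative to it.
#' @param imaging_tolerance Allowed deviation from `target_time`, seconds.
#' @param prep_duration Gantry seconds per mixture-preparation batch.
#' @return An `lfa_protocol`.
#' @export
assay_protocol <- function(..., imaging_tolerance = 60, prep_duration = 15) {
  steps <- list(...)
  if (length(steps) == 1L && !inherits(steps[[1]], "lfa_step"))
    steps <- steps[[1]]
  if (!length(steps) || !all(vapply(steps, inherits, TRUE, "lfa_step")))
    stop("assay_protocol() needs protocol_step objects", call. = FALSE)
  actions <- vapply(steps, `[[`, "", "action")
  if (any(actions == "image") && sum(actions == "dispense_sample") != 1L)
    stop("protocols with image steps need exactly one dispense_sample step",
         call. = FALSE)
  stopifnot(imaging_tolerance >= 0, prep_duration > 0)
  structure(list(steps = steps, imaging_tolerance = imaging_tolerance,
                 prep_duration = prep_duration),
            class = "lfa_protocol")
}

#' @export
print.lfa_protocol <- function(x, ...) {
  cat("LFA protocol:", length(x$steps), "steps, imaging tolerance +/-",
      x$imaging_tolerance, "s\n")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  %d. %-16s", i, s$action))
    if (s$action == "image") cat(" at sample +", s$target_time, "s")
    else cat(" ", s$volume, "uL ->", s$destination)
    if (s$min_delay > 0) cat("  (>=", s$min_delay, "s after previous)")
    cat("\n")
  }
  invisible(x)
}

dialect_cols <- c("run", "batch", "channel", "action", "source_labware",
                  "source_pos", "dest_holder", "dest_slot", "dest_well",
                  "volume_ul", "liquid_class", "scheduled_start_s",
                  "condition_id")
numeric_dialect_cols <- c("run", "batch", "channel", "dest_slot", "volume_ul",
                          "scheduled_start_s")

#' Expand a protocol over the conditions of one run
#'
#' Produces one unscheduled transfer per (condition, liquid step), one
#' imaging event per (condition, image step), and -- for reagents backed by a
#' mixture recipe -- the preparation transfers that must precede first use
#' (on-deck preparation; `prepare` rows draw from stocks into a mix tube).
#'
#' @param conditions Condition table for a single run, with `holder_id` and
#'   `slot_index` columns (see [split_into_runs()]).
#' @param protocol An [assay_protocol()].
#' @param reagents Named list resolving reagent keys: each element either a
#'   character stock id (direct dispense from `stocks` labware) or an
#'   `lfa_recipe` (dispense from a prepared mix tube).
#' @return data.frame of unscheduled events (internal schema; feed to
#'   [batch_transfers()] then [schedule_run()]).
#' @export
expand_protocol <- function(conditions, protocol, reagents = list()) {
  stopifnot(inherits(protocol, "lfa_protocol"), is.data.frame(conditions))
  if (!all(c("condition_id", "holder_id", "slot_index") %in% names(conditions)))
    stop("conditions need condition_id/holder_id/slot_index columns ",
         "(run split_into_runs() first)", call. = FALSE)
  run <- if (!is.null(conditions$run_index) && nrow(conditions))
    conditions$run_index[1] else 1L
  rows <- list()
  used_mixes <- character()
  for (j in seq_along(protocol$steps)) {
    s <- protocol$steps[[j]]
    for (i in seq_len(nrow(conditions))) {
      cond <- conditions[i, , drop = FALSE]
      if (s$action == "image") {
        rows[[length(rows) + 1L]] <- data.frame(
          condition_id = cond$condition_id, step_index = j, action = "image",
          source_labware = "", source_pos = "",
          dest_holder = cond$holder_id, dest_slot = cond$slot_index,
          dest_well = "", volume = NA_real_, liquid_class = "",
          min_delay = s$min_delay, target_time = s$target_time,
          duration = s$duration, run_index = run, stringsAsFactors = FALSE)
        next
      }
      key <- if (is.function(s$reagent)) s$reagent(cond) else s$reagent
      if (is.null(key) || !is.character(key) || !nzchar(key))
        stop("cannot resolve reagent for condition '", cond$condition_id,
             "' at step ", j, call. = FALSE)
      res <- reagents[[key]]
      if (is.null(res))
        stop("cannot resolve reagent '", key, "' for condition '",
             cond$condition_id, "' at step ", j, call. = FALSE)
      if (inherits(res, "lfa_recipe")) {
        src_lab <- "mixes"; src_pos <- key
        used_mixes <- union(used_mixes, key)
      } else {
        src_lab <- "stocks"; src_pos <- as.character(res)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition_id = cond$condition_id, step_index = j, action = s$action,
        source_labware = src_lab, source_pos = src_pos,
        dest_holder = cond$holder_id, dest_slot = cond$slot_index,
        dest_well = s$destination, volume = s$volume,
        liquid_class = s$liquid_class, min_delay = s$min_delay,
        target_time = NA_real_, duration = s$duration, run_index = run,
        stringsAsFactors = FALSE)
    }
  }
  prep <- list()
  for (key in used_mixes) {
    rec <- reagents[[key]]
    tr <- rec$transfers
    if (rec$diluent_volume > 0)
      tr <- rbind(tr, data.frame(stock_id = "buffer", component = ".diluent",
                                 volume = rec$diluent_volume,
                                 stringsAsFactors = FALSE))
    tr <- tr[tr$volume > 0, , drop = FALSE]
    if (nrow(tr))
      prep[[length(prep) + 1L]] <- data.frame(
        condition_id = "", step_index = 0L, action = "prepare",
        source_labware = "stocks", source_pos = tr$stock_id,
        dest_holder = "mixes", dest_slot = match(key, used_mixes),
        dest_well = key, volume = tr$volume, liquid_class = "Prep",
        min_delay = 0, target_time = NA_real_,
        duration = protocol$prep_duration, run_index = run,
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(prep, rows))
  if (is.null(out)) out <- empty_events()
  rownames(out) <- NULL
  out
}

empty_events <- function() {
  data.frame(condition_id = character(), step_index = integer(),
             action = character(), source_labware = character(),
             source_pos = character(), dest_holder = character(),
             dest_slot = integer(), dest_well = character(),
             volume = numeric(), liquid_class = character(),
             min_delay = numeric(), target_time = numeric(),
             duration = numeric(), run_index = integer(),
             stringsAsFactors = FALSE)
}

#' Group transfers into multi-channel batches
#'
#' Transfers sharing step, source labware class, volume and liquid class are
#' filled greedily (in event order) into batches of at most `n_channels`, one
#' channel per transfer. Imaging events are grouped by the batch that
#' dispensed their strips' sample, so strips pipetted together are imaged
#' together (their imaging deadlines coincide).
#'
#' @param events Output of [expand_protocol()].
#' @param n_channels Number of independent pipetting channels (>= 1).
#' @return `events` with `batch_id` and `channel` columns.
#' @export
batch_transfers <- function(events, n_channels = 8) {
  n_channels <- as.integer(n_channels)
  stopifnot(n_channels >= 1L)
  events$batch_id <- rep(NA_integer_, nrow(events))
  events$channel <- rep(NA_integer_, nrow(events))
  liquid <- which(events$action != "image")
  key <- paste(events$step_index[liquid], events$source_labware[liquid],
               format(events$volume[liquid]), events$liquid_class[liquid],
               sep = "\r")
  next_id <- 0L
  for (k in unique(key)) {
    idx <- liquid[key == k]
    nb <- ceiling(length(idx) / n_channels)
    events$batch_id[idx] <- next_id + rep(seq_len(nb), each = n_channels)[seq_along(idx)]
    events$channel[idx] <- rep(seq_len(n_channels), nb)[seq_along(idx)]
    next_id <- next_id + nb
  }
  img <- which(events$action == "image")
  if (length(img)) {
    smp <- which(events$action == "dispense_sample")
    sample_batch <- events$batch_id[smp][match(events$condition_id[img],
                                               events$condition_id[smp])]
    if (anyNA(sample_batch))
      stop("image events without a sample dispense for the same strip",
           call. = FALSE)
    gkey <- paste(events$step_index[img], sample_batch, sep = "\r")
    for (k in unique(gkey)) {
      idx <- img[gkey == k]
      next_id <- next_id + 1L
      events$batch_id[idx] <- next_id
      events$channel[idx] <- seq_along(idx)
    }
  }
  events
}

# per-batch summary used by the scheduler
batch_table <- function(events) {
  ids <- sort(unique(events$batch_id))
  data.frame(
    batch_id = ids,
    step_index = events$step_index[match(ids, events$batch_id)],
    action = events$action[match(ids, events$batch_id)],
    duration = events$duration[match(ids, events$batch_id)],
    min_delay = events$min_delay[match(ids, events$batch_id)],
    target_time = events$target_time[match(ids, events$batch_id)],
    stringsAsFactors = FALSE)
}

#' Schedule a batched run into a timed worklist
#'
#' Earliest-deadline-first over a single gantry: at most one batch executes
#' at a time, each occupying the gantry for its step duration. For every
#' strip, step j starts at least `min_delay` seconds after step j-1's start;
#' preparation batches precede the first use of their mixture; imaging
#' batches must start within `imaging_tolerance` of the strip's
#' `sample time + target_time` or scheduling aborts with a suggested smaller
#' run size. Ties are broken by step index then batch id, so the schedule is
#' deterministic. Time zero is the first batch start.
#'
#' @param events Output of [batch_transfers()].
#' @param protocol The [assay_protocol()] the events were expanded from.
#' @param deck Optional [deck_layout()]; when given, runs holding more strips
#'   than `run_capacity` are refused.
#' @return An `lfa_worklist`.
#' @export
schedule_run <- function(events, protocol, deck = NULL) {
  stopifnot(inherits(protocol, "lfa_protocol"))
  if (is.null(events$batch_id))
    stop("events are not batched; call batch_transfers() first", call. = FALSE)
  conds <- setdiff(unique(events$condition_id), "")
  if (!is.null(deck) && length(conds) > deck$run_capacity)
    stop("run holds ", length(conds), " strips but deck capacity is ",
         deck$run_capacity, "; split the experiment into more runs",
         call. = FALSE)
  run <- if (nrow(events)) events$run_index[1] else 1L
  tol <- protocol$imaging_tolerance
  if (nrow(events) == 0L) {
    wl <- new_worklist(run, events_to_dialect(events), protocol)
    return(wl)
  }

  bt <- batch_table(events)
  nb <- nrow(bt)
  start <- rep(NA_real_, nb)          # scheduled batch starts
  release <- rep(NA_real_, nb)
  # per (condition, protocol step) start times for the precedence chain
  step_start <- matrix(NA_real_, nrow = length(conds),
                       ncol = length(protocol$steps),
                       dimnames = list(conds, NULL))
  prep_finish <- c()                  # named by mix key
  members <- split(seq_len(nrow(events)), events$batch_id)
  members <- members[as.character(bt$batch_id)]

  # sample dispense times per condition (filled as sample batches schedule)
  sample_step <- which(vapply(protocol$steps, `[[`, "", "action") == "dispense_sample")
  sample_time <- stats::setNames(rep(NA_real_, length(conds)), conds)

  readiness <- function(b) {
    rows <- members[[b]]
    act <- bt$action[b]
    if (act == "prepare") return(0)
    j <- bt$step_index[b]
    cids <- events$condition_id[rows]
    rel <- 0
    if (j > 1L) {
      prev <- step_start[cids, j - 1L]
      if (anyNA(prev)) return(NA_real_)
      rel <- max(prev) + bt$min_delay[b]
    }
    if (act == "image") {
      st <- sample_time[cids]
      if (anyNA(st)) return(NA_real_)
      rel <- max(rel, max(st) + bt$target_time[b] - tol)
    } else {
      mixes <- unique(events$source_pos[rows][events$source_labware[rows] == "mixes"])
      if (length(mixes)) {
        if (!all(mixes %in% names(prep_finish))) return(NA_real_)
        rel <- max(rel, max(prep_finish[mixes]))
      }
    }
    rel
  }

  t_free <- 0
  pending <- rep(TRUE, nb)
  while (any(pending)) {
    for (b in which(pending)) release[b] <- readiness(b)
    ready <- which(pending & !is.na(release))
    if (!length(ready))
      stop("scheduling deadlock: circular or unsatisfiable precedence",
           call. = FALSE)
    dl <- ifelse(bt$action[ready] == "image",
                 vapply(ready, function(b) {
                   cids <- events$condition_id[members[[b]]]
                   max(sample_time[cids]) + bt$target_time[b] + tol
                 }, 0), Inf)
    ord <- order(dl, release[ready], bt$step_index[ready], bt$batch_id[ready])
    pick <- ready[ord[1]]
    s <- max(t_free, release[pick])
    if (s > t_free && length(ready) > 1L) {
      # fill gantry idle time with another ready batch that finishes in time
      for (b in ready[ord[-1]]) {
        fs <- max(t_free, release[b])
        if (fs + bt$duration[b] <= s + 1e-9) { pick <- b; s <- fs; break }
      }
    }
    if (bt$action[pick] == "image") {
      cids <- events$condition_id[members[[pick]]]
      deadline <- max(sample_time[cids]) + bt$target_time[pick] + tol
      if (s > deadline + 1e-9) {
        n_strips <- length(conds)
        suggest <- max(1L, floor(n_strips * (2 * tol) /
                                   (2 * tol + (s - deadline))))
        stop(sprintf(paste0("infeasible imaging schedule: batch %d misses its ",
                            "window by %.0f s; try splitting into runs of ",
                            "<= %d strips"),
                     bt$batch_id[pick], s - deadline, suggest), call. = FALSE)
      }
    }
    start[pick] <- s
    rows <- members[[pick]]
    cids <- events$condition_id[rows]
    if (bt$action[pick] == "prepare") {
      prep_finish[unique(events$dest_well[rows])] <- s + bt$duration[pick]
    } else {
      step_start[cids, bt$step_index[pick]] <- s
      if (length(sample_step) && bt$step_index[pick] == sample_step)
        sample_time[cids] <- s
    }
    t_free <- s + bt$duration[pick]
    pending[pick] <- FALSE
  }

  events$earliest_start <- release[match(events$batch_id, bt$batch_id)]
  events$scheduled_start <- start[match(events$batch_id, bt$batch_id)]
  events <- events[order(events$scheduled_start, events$batch_id,
                         events$channel), , drop = FALSE]
  rownames(events) <- NULL
  new_worklist(run, events_to_dialect(events), protocol)
}

events_to_dialect <- function(events) {
  data.frame(run = as.integer(events$run_index),
             batch = as.integer(events$batch_id),
             channel = as.integer(events$channel), action = events$action,
             source_labware = events$source_labware,
             source_pos = events$source_pos,
             dest_holder = as.character(events$dest_holder),
             dest_slot = as.numeric(events$dest_slot),
             dest_well = events$dest_well,
             volume_ul = events$volume, liquid_class = events$liquid_class,
             scheduled_start_s = events$scheduled_start,
             condition_id = events$condition_id, stringsAsFactors = FALSE)
}

obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

new_worklist <- function(run, table, protocol) {
  structure(list(run_index = run, events = table,
                 imaging_tolerance = protocol$imaging_tolerance,
                 prep_duration = protocol$prep_duration,
                 protocol_hash = obj_hash(protocol$steps)),
            class = "lfa_worklist")
}

#' @export
print.lfa_worklist <- function(x, ...) {
  ev <- x$events
  cat("Worklist for run", x$run_index, "-", nrow(ev), "events (",
      sum(ev$action != "image"), "transfers,", sum(ev$action == "image"),
      "imaging ) over",
      if (nrow(ev)) max(ev$scheduled_start_s) else 0, "s\n")
  invisible(x)
}

#' Write a worklist to its CSV dialect
#'
#' UTF-8, comma-separated, fixed header
#' `run,batch,channel,action,source_labware,source_pos,dest_holder,dest_slot,dest_well,volume_ul,liquid_class,scheduled_start_s,condition_id`;
#' one row per transfer or imaging event, imaging rows with blank
#' volume/source. Round-trips bit-exactly through [read_worklist()].
#'
#' @param worklist An `lfa_worklist`.
#' @param path Output file.
#' @export
write_worklist <- function(worklist, path) {
  ev <- worklist$events[, dialect_cols, drop = FALSE]
  fmt <- function(x) {
    out <- if (is.numeric(x)) as.character(x) else x
    out[is.na(x)] <- ""
    out
  }
  body <- do.call(paste, c(lapply(ev, fmt), sep = ","))
  writeLines(c(paste(dialect_cols, collapse = ","), body), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a worklist from its CSV dialect
#'
#' @param path CSV file written by [write_worklist()].
#' @return An `lfa_worklist` (metadata fields not stored in the CSV --
#'   tolerance, hashes -- are absent; pass the protocol to
#'   [simulate_worklist()] to validate).
#' @export
read_worklist <- function(path) {
  ev <- utils::read.csv(path, colClasses = "character", na.strings = NULL)
  if (!identical(names(ev), dialect_cols))
    stop("not a worklist CSV: unexpected header", call. = FALSE)
  for (cc in numeric_dialect_cols) {
    v <- ev[[cc]]
    v[v == ""] <- NA
    ev[[cc]] <- as.numeric(v)
  }
  ev$batch <- as.integer(ev$batch)
  ev$channel <- as.integer(ev$channel)
  ev$run <- as.integer(ev$run)
  structure(list(run_index = if (nrow(ev)) ev$run[1] else NA_integer_,
                 events = ev),
            class = "lfa_worklist")
}

#' Replay a worklist on a virtual timeline and report violations
#'
#' Independent discrete-event check of a worklist (typically parsed back from
#' CSV): per-strip step order and minimum delays, imaging windows relative to
#' each strip's sample dispense, single-gantry batch overlap, and running
#' stock balances. Violations are report rows, never exceptions.
#'
#' @param worklist An `lfa_worklist`.
#' @param protocol The [assay_protocol()] defining step order, delays,
#'   durations and the imaging tolerance.
#' @param stocks Optional [stock_table()]; enables stock-depletion checks
#'   against `volume` available per stock.
#' @return An `lfa_feasibility`: `feasible` flag plus a `violations`
#'   data.frame (`type`, `detail`).
#' @export
simulate_worklist <- function(worklist, protocol, stocks = NULL) {
  ev <- worklist$events
  tol <- protocol$imaging_tolerance
  viol <- list()
  add <- function(type, detail)
    viol[[length(viol) + 1L]] <<- data.frame(type = type, detail = detail,
                                             stringsAsFactors = FALSE)
  actions <- vapply(protocol$steps, `[[`, "", "action")
  durations <- vapply(protocol$steps, `[[`, 0, "duration")
  delays <- vapply(protocol$steps, `[[`, 0, "min_delay")
  targets <- vapply(protocol$steps, `[[`, 0, "target_time")
  sample_step <- which(actions == "dispense_sample")

  batch_dur <- numeric(0)
  cond_rows <- split(seq_len(nrow(ev)), ev$condition_id)
  for (cid in names(cond_rows)) {
    rows <- cond_rows[[cid]]
    if (cid == "") {                      # preparation rows
      batch_dur[as.character(ev$batch[rows])] <-
        if (!is.null(worklist$prep_duration)) worklist$prep_duration
        else protocol$prep_duration
      next
    }
    rows <- rows[order(ev$scheduled_start_s[rows], ev$batch[rows])]
    if (length(rows) != length(actions)) {
      add("step_count", sprintf("strip %s has %d events, protocol has %d steps",
                                cid, length(rows), length(actions)))
      next
    }
    if (!all(ev$action[rows] == actions)) {
      add("step_order", sprintf("strip %s executes steps out of protocol order",
                                cid))
      next
    }
    st <- ev$scheduled_start_s[rows]
    batch_dur[as.character(ev$batch[rows])] <- durations
    lag <- diff(st)
    late <- which(lag < delays[-1] - 1e-9)
    for (j in late)
      add("min_delay", sprintf("strip %s step %d starts %.1f s after step %d (min %.0f s)",
                               cid, j + 1L, lag[j], j, delays[j + 1L]))
    if (length(sample_step)) {
      t_sample <- st[sample_step]
      for (j in which(actions == "image")) {
        dev <- st[j] - (t_sample + targets[j])
        if (abs(dev) > tol + 1e-9)
          add("imaging_window",
              sprintf("strip %s imaged %.1f s from target (tolerance +/- %.0f s)",
                      cid, dev, tol))
      }
    }
  }

  # single gantry: batch intervals must not overlap
  b <- sort(unique(ev$batch))
  bstart <- vapply(b, function(bb) {
    s <- unique(ev$scheduled_start_s[ev$batch == bb])
    if (length(s) > 1L)
      add("batch_sync", sprintf("batch %d rows have differing start times", bb))
    min(s)
  }, 0)
  bdur <- batch_dur[as.character(b)]
  bdur[is.na(bdur)] <- 0
  o <- order(bstart, b)
  fin <- bstart[o] + bdur[o]
  over <- which(bstart[o][-1] < fin[-length(fin)] - 1e-9)
  for (j in over)
    add("gantry_overlap",
        sprintf("batch %d starts at %.1f s before batch %d ends at %.1f s",
                b[o][j + 1L], bstart[o][j + 1L], b[o][j], fin[j]))

  if (!is.null(stocks)) {
    draws <- ev[ev$source_labware == "stocks" & !is.na(ev$volume_ul), ,
                drop = FALSE]
    for (sid in unique(draws$source_pos)) {
      avail <- stocks$volume[match(sid, stocks$stock_id)]
      if (is.na(avail)) next
      tot <- sum(draws$volume_ul[draws$source_pos == sid])
      if (tot > avail + 1e-9)
        add("stock_depletion",
            sprintf("stock %s: %.1f uL drawn but only %.1f uL available",
                    sid, tot, avail))
    }
  }

  viol <- if (length(viol)) do.call(rbind, viol)
  else data.frame(type = character(), detail = character(),
                  stringsAsFactors = FALSE)
  structure(list(feasible = nrow(viol) == 0L, violations = viol),
            class = "lfa_feasibility")
}

#' @export
print.lfa_feasibility <- function(x, ...) {
  if (x$feasible) cat("feasible\n")
  else {
    cat("INFEASIBLE:", nrow(x$violations), "violation(s)\n")
    for (i in seq_len(min(nrow(x$violations), 20)))
      cat("  [", x$violations$type[i], "] ", x$violations$detail[i], "\n",
          sep = "")
  }
  invisible(x)
}
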