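test_that("protocol expansion yields one event per condition-step pair", {
  proto <- std_protocol()
  run2 <- strip_run(2)
  ev <- expand_protocol(run2, proto, std_reagents())
  expect_equal(sum(ev$action != "image"), 4L)
  expect_equal(sum(ev$action == "image"), 2L)

  run96 <- strip_run(96)
  proto2 <- assay_protocol(
    protocol_step("dispense_reagent", reagent = "conjugate", volume = 10),
    protocol_step("dispense_sample", reagent = "sample", volume = 50))
  ev96 <- expand_protocol(run96, proto2, std_reagents())
  expect_equal(nrow(ev96), 192L)

  expect_error(expand_protocol(run2, proto, list(sample = "s")),
               "cannot resolve reagent 'conjugate' for condition 'strip=S001;rep=1' at step 1")
})

test_that("a shared mixture is prepared once, before first use", {
  st <- stock_table(c("A240", "B240"), c("A", "B"), 240, volume = 5000)
  rec <- plan_mixture(c(A = 15, B = 30), st, 500, target_id = "conj_mix")
  proto <- std_protocol()
  run8 <- strip_run(8)
  ev <- expand_protocol(run8, proto,
                        list(conjugate = rec, sample = "sample_stock"))
  prep <- ev[ev$action == "prepare", ]
  expect_equal(nrow(prep), 3L)          # A + B + diluent
  expect_setequal(prep$source_pos, c("A240", "B240", "buffer"))
  expect_equal(sum(ev$source_labware == "mixes"), 8L)

  wl <- schedule_run(batch_transfers(ev), proto)
  evs <- wl$events
  prep_end <- max(evs$scheduled_start_s[evs$action == "prepare"])
  first_use <- min(evs$scheduled_start_s[evs$source_labware == "mixes"])
  expect_lt(prep_end, first_use + 1e-9)
  expect_true(simulate_worklist(wl, proto, st)$feasible)
})

test_that("channel batching fills greedily without mixing incompatible transfers", {
  proto1 <- assay_protocol(
    protocol_step("dispense_sample", reagent = "sample", volume = 50))
  ev16 <- batch_transfers(expand_protocol(strip_run(16), proto1,
                                          std_reagents()))
  expect_equal(length(unique(ev16$batch_id)), 2L)
  expect_equal(as.integer(table(ev16$batch_id)), c(8L, 8L))

  ev13 <- batch_transfers(expand_protocol(strip_run(13), proto1,
                                          std_reagents()))
  expect_equal(sort(as.integer(table(ev13$batch_id))), c(5L, 8L))
  expect_true(all(ev13$channel <= 8))

  # two volumes never share a batch
  run16 <- strip_run(16)
  protoV <- assay_protocol(
    protocol_step("dispense_sample",
                  reagent = function(cond)
                    if (cond$slot_index %% 2 == 0) "sampleA" else "sampleB",
                  volume = 50))
  evV <- expand_protocol(run16, protoV,
                         list(sampleA = "stkA", sampleB = "stkB"))
  evV$volume[evV$source_pos == "stkA"] <- 25
  evV <- batch_transfers(evV)
  vols_per_batch <- tapply(evV$volume, evV$batch_id,
                           function(v) length(unique(v)))
  expect_true(all(vols_per_batch == 1L))
  src_per_batch <- tapply(paste(evV$step_index, evV$liquid_class),
                          evV$batch_id, function(v) length(unique(v)))
  expect_true(all(src_per_batch == 1L))
})

test_that("scheduling honours per-strip delays and imaging windows", {
  proto <- std_protocol()        # delays {0, 120}, image at 1800 +/- 60
  wl <- schedule_run(batch_transfers(expand_protocol(strip_run(1), proto,
                                                     std_reagents())), proto)
  ev <- wl$events[order(wl$events$scheduled_start_s), ]
  expect_equal(ev$scheduled_start_s[1], 0)
  expect_gte(ev$scheduled_start_s[2], 120)
  t_sample <- ev$scheduled_start_s[ev$action == "dispense_sample"]
  t_image <- ev$scheduled_start_s[ev$action == "image"]
  expect_lte(abs(t_image - (t_sample + 1800)), 60)

  empty <- schedule_run(batch_transfers(expand_protocol(strip_run(1)[0, ],
                                                        proto,
                                                        std_reagents())),
                        proto)
  expect_equal(nrow(empty$events), 0L)
})

test_that("a 24-strip run passes the discrete-event simulator end to end", {
  proto <- std_protocol()
  run24 <- strip_run(24)
  wl <- schedule_run(batch_transfers(expand_protocol(run24, proto,
                                                     std_reagents())), proto)
  rep <- simulate_worklist(wl, proto)
  expect_true(rep$feasible)
  expect_equal(nrow(rep$violations), 0L)
  expect_worklist_bijection(wl, proto, run24)
  # all 24 imaging events inside the window, checked directly too
  ev <- wl$events
  for (cid in run24$condition_id) {
    rows <- ev[ev$condition_id == cid, ]
    dev <- rows$scheduled_start_s[rows$action == "image"] -
      (rows$scheduled_start_s[rows$action == "dispense_sample"] + 1800)
    expect_lte(abs(dev), 60)
  }
})

test_that("scheduling is deterministic and refuses oversized runs", {
  proto <- std_protocol()
  ev <- batch_transfers(expand_protocol(strip_run(24), proto, std_reagents()))
  w1 <- schedule_run(ev, proto)
  w2 <- schedule_run(ev, proto)
  expect_identical(w1$events, w2$events)

  small_deck <- deck_layout(data.frame(holder_id = "H1", strip_capacity = 16))
  big <- batch_transfers(expand_protocol(strip_run(24), proto, std_reagents()))
  expect_error(schedule_run(big, proto, small_deck), "deck capacity")
})

test_that("the simulator reports constructed violations", {
  proto <- std_protocol()
  wl <- schedule_run(batch_transfers(expand_protocol(strip_run(8), proto,
                                                     std_reagents())), proto)
  # gantry overlap: drag the second batch onto the first
  tampered <- wl
  b <- sort(unique(tampered$events$batch))
  sel <- tampered$events$batch == b[2]
  tampered$events$scheduled_start_s[sel] <-
    min(tampered$events$scheduled_start_s) + 1
  rep <- simulate_worklist(tampered, proto)
  expect_false(rep$feasible)
  expect_true("gantry_overlap" %in% rep$violations$type)

  # min-delay violation on the dragged sample dispenses
  expect_true(any(rep$violations$type %in% c("min_delay", "imaging_window")))

  # stock depletion: 8 x 50 uL sample draws against 150 uL available
  st <- stock_table(c("conj_stock", "sample_stock"), c("conj", "smp"),
                    c(100, 100), volume = c(1e6, 150))
  rep2 <- simulate_worklist(wl, proto, st)
  expect_false(rep2$feasible)
  expect_true("stock_depletion" %in% rep2$violations$type)
  expect_match(rep2$violations$detail[rep2$violations$type == "stock_depletion"],
               "sample_stock")
})

test_that("infeasible imaging deadlines abort with a smaller-run suggestion", {
  # imaging takes far longer than sample dispensing: deadlines pile up
  proto <- assay_protocol(
    protocol_step("dispense_sample", reagent = "sample", volume = 50,
                  duration = 5),
    protocol_step("image", target_time = 600, duration = 300),
    imaging_tolerance = 30)
  ev <- batch_transfers(expand_protocol(strip_run(48), proto, std_reagents()))
  expect_error(schedule_run(ev, proto), "splitting into runs of <=")
})

test_that("worklists round-trip bit-exactly through the CSV dialect", {
  st <- stock_table(c("A240", "B240"), c("A", "B"), 240, volume = 5000)
  rec <- plan_mixture(c(A = 15, B = 30), st, 500, target_id = "mix")
  proto <- std_protocol()
  wl <- schedule_run(batch_transfers(expand_protocol(
    strip_run(13), proto, list(conjugate = rec, sample = "sample_stock"))),
    proto)
  f <- withr::local_tempfile(fileext = ".csv")
  write_worklist(wl, f)
  wl2 <- read_worklist(f)
  expect_identical(wl$events, wl2$events)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_worklist(wl2, f2)
  expect_identical(readLines(f), readLines(f2))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b,c", bad)
  expect_error(read_worklist(bad), "unexpected header")
})

test_that("feasibility closure holds for randomly generated runs", {
  set.seed(101)
  for (i in 1:12) {
    n_liquid <- sample(1:3, 1)
    steps <- lapply(seq_len(n_liquid), function(j)
      protocol_step(if (j < n_liquid) "dispense_reagent" else "dispense_sample",
                    reagent = if (j < n_liquid) "conjugate" else "sample",
                    volume = sample(5:80, 1),
                    min_delay = sample(c(0, 30, 120), 1),
                    duration = sample(10:30, 1)))
    steps <- c(steps, list(protocol_step("image",
                                         target_time = sample(c(1800, 2100), 1),
                                         duration = sample(2:10, 1))))
    proto <- assay_protocol(steps, imaging_tolerance = 60)
    run <- strip_run(sample(4:96, 1))
    wl <- schedule_run(batch_transfers(expand_protocol(run, proto,
                                                       std_reagents())),
                       proto, std_deck())
    rep <- simulate_worklist(wl, proto)
    expect_true(rep$feasible,
                info = paste("case", i, ":",
                             paste(rep$violations$detail, collapse = "; ")))
    expect_worklist_bijection(wl, proto, run)
  }
})
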