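make_two_strand_topo <- function() {
  make_topology(list(a = oligomer("ACGT", "a"), b = oligomer("ACGT", "b")))
}

test_that("frame_pair_overlap scores antiparallel runs and isolated bonds", {
  topo <- make_two_strand_topo()            # a: 0..3, b: 4..7
  run3 <- hb_frame(0, rbind(c(0, 7), c(1, 6), c(2, 5)))
  expect_equal(frame_pair_overlap(run3, topo, "a", "b"), c(mco = 3L, tmo = 3L))
  isolated <- hb_frame(0, rbind(c(0, 7), c(2, 5)))
  expect_equal(frame_pair_overlap(isolated, topo, "a", "b"),
               c(mco = 1L, tmo = 2L))
  expect_equal(frame_pair_overlap(hb_frame(0), topo, "a", "b"),
               c(mco = 0L, tmo = 0L))
  # parallel-register bonds count toward TMO only
  parallel <- hb_frame(0, rbind(c(0, 4), c(1, 5), c(2, 6)))
  expect_equal(frame_pair_overlap(parallel, topo, "a", "b"),
               c(mco = 1L, tmo = 3L))
  expect_error(frame_pair_overlap(run3, topo, "a", "z"), "unknown strand")
  expect_error(frame_pair_overlap(run3, topo, "a", "a"), "different strands")
})

test_that("bonds with third strands never leak into a pair's statistics", {
  topo <- make_topology(list(a = oligomer("ACGT", "a"),
                             b = oligomer("ACGT", "b"),
                             c = oligomer("ACGT", "c")))
  fr <- hb_frame(0, rbind(c(0, 7), c(1, 6), c(2, 9)))  # last bond is a-c
  expect_equal(frame_pair_overlap(fr, topo, "a", "b"), c(mco = 2L, tmo = 2L))
  expect_equal(frame_pair_overlap(fr, topo, "a", "c"), c(mco = 1L, tmo = 1L))
})

test_that("histograms count frames with a 0 bin and pool runs with equal weight", {
  tr <- structure(list(pair = c("a", "b"), steps = c(0, 1e3, 2e3, 3e3),
                       mco = c(4L, 4L, 0L, 4L), tmo = c(4L, 6L, 0L, 4L)),
                  class = "pair_trace")
  h <- overlap_histogram(tr)
  expect_equal(unname(h$p_mco[c("0", "4")]), c(0.25, 0.75))
  expect_equal(sum(h$p_mco), 1)
  expect_equal(sum(h$p_tmo), 1)
  expect_equal(h$n_frames_total, 4L)
  # equal-length runs pool to the average of per-run histograms
  tr2 <- structure(list(pair = c("a", "b"), steps = tr$steps,
                        mco = c(2L, 2L, 2L, 2L), tmo = c(2L, 2L, 2L, 2L)),
                   class = "pair_trace")
  pooled <- overlap_histogram(list(tr, tr2))
  expect_equal(pooled$n_runs, 2L)
  at <- function(p, v) ifelse(is.na(p[as.character(v)]), 0, p[as.character(v)])
  for (v in 0:4)
    expect_equal(unname(at(pooled$p_mco, v)),
                 unname((at(h$p_mco, v) + at(overlap_histogram(tr2)$p_mco, v)) / 2))
  expect_error(overlap_histogram(list()), "no traces")
})

test_that("ensemble averaging is pointwise over runs and demands one step grid", {
  mk <- function(mco, steps = c(0, 1e3, 2e3))
    structure(list(pair = c("a", "b"), steps = steps, mco = mco,
                   tmo = mco), class = "pair_trace")
  ts <- ensemble_timeseries(list(mk(c(4, 4, 4)), mk(c(0, 0, 0))))
  expect_equal(ts$mean_mco, c(2, 2, 2))
  expect_equal(attr(ts, "n_runs"), 2L)
  one <- ensemble_timeseries(mk(c(1, 2, 3)))
  expect_equal(one$mean_mco, c(1, 2, 3))
  expect_error(ensemble_timeseries(list(mk(c(1, 1, 1)),
                                        mk(c(1, 1, 1), steps = c(0, 500, 1000)))),
               "resample")
})

test_that("binding events cover thresholded runs, with exclusive end steps", {
  tr <- structure(list(pair = c("a", "b"),
                       steps = c(0, 1e3, 2e3, 3e3, 4e3),
                       mco = c(4L, 5L, 4L, 0L, 4L),
                       tmo = c(4L, 5L, 4L, 0L, 4L)), class = "pair_trace")
  ev <- binding_events(tr, threshold = 4)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$lifetime_steps, c(3e3, 1e3))
  expect_true(ev$censored_right[2])
  expect_false(ev$censored_right[1])
  expect_true(ev$censored_left[1])          # starts at the trace's first frame
  expect_equal(ev$end_step[1], 3e3)

  none <- binding_events(structure(list(pair = c("a", "b"), steps = c(0, 1e3),
                                        mco = c(0L, 0L), tmo = c(0L, 0L)),
                                   class = "pair_trace"))
  expect_equal(nrow(none), 0L)
})

test_that("events and gaps reconstruct the thresholded trace exactly", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 60L
    mco <- sample(0:6, n, replace = TRUE)
    tr <- structure(list(pair = c("a", "b"), steps = (0:(n - 1)) * 1e3,
                         mco = mco, tmo = mco), class = "pair_trace")
    thr <- sample(1:5, 1)
    ev <- binding_events(tr, threshold = thr)
    rebuilt <- rep(FALSE, n)
    for (i in seq_len(nrow(ev))) {
      f0 <- ev$start_step[i] / 1e3 + 1L
      rebuilt[f0:(f0 + ev$n_frames[i] - 1L)] <- TRUE
    }
    expect_identical(rebuilt, mco >= thr)
    expect_equal(ev$lifetime_steps, ev$n_frames * 1e3)
  }
})

test_that("complex detection labels the trimer and tetramer worked examples", {
  oli <- builtin_oligomers()
  topo3 <- make_topology(oli[c("p4", "p10", "res")])  # p4 0-49, p10 50-99, res 100-119
  # p10-res and p4-p10 bonds only: the parasite trimer
  fr <- hb_frame(0, rbind(c(50, 119), c(0, 60)))
  comp <- detect_complexes(fr, topo3)$components
  expect_equal(nrow(comp), 1L)
  expect_equal(comp$size_class, "trimer")
  expect_equal(comp$composition, "p10+p4+res")

  # two resources bridged by p10, p4 on p10's other end: tetramer
  oli4 <- setNames(oli[c("res", "p10", "res", "p4")],
                   c("res1", "p10", "res2", "p4"))
  topo4 <- make_topology(oli4)               # res1 0-19, p10 20-69, res2 70-89, p4 90-139
  fr4 <- hb_frame(0, rbind(c(0, 20), c(30, 70), c(60, 90)))
  comp4 <- detect_complexes(fr4, topo4,
                            species = c("res", "p10", "res", "p4"))$components
  expect_equal(nrow(comp4), 1L)
  expect_equal(comp4$size_class, "tetramer")
  expect_equal(comp4$composition, "p10+p4+2xres")

  # no bonds: all singletons, partitioning the strand set
  empty <- detect_complexes(hb_frame(0), topo3)$components
  expect_equal(nrow(empty), 3L)
  expect_true(all(empty$size_class == "monomer"))
})

test_that("every strand lands in exactly one component per frame", {
  cfg <- scenario_preset("competition3", n_frames = 80, rng_seed = 3)
  sim <- generate_competition(cfg)
  for (fr in sim$frames[seq(1, 80, by = 8)]) {
    comp <- detect_complexes(fr, sim$topology)$components
    members <- unlist(strsplit(comp$members, ","))
    expect_setequal(members, sim$topology$strand_names)
    expect_false(anyDuplicated(members) > 0)
  }
})

test_that("complex occupancy fractions form a simple tally summing to 1", {
  cfg <- scenario_preset("competition3", n_frames = 120, rng_seed = 8)
  sim <- generate_competition(cfg)
  rep <- complex_report(sim$frames, sim$topology)
  expect_equal(sum(rep$occupancy$fraction), 1)
  expect_length(rep$per_frame, 120L)
})

test_that("self_fold counts loop-compatible intra-strand pairs", {
  topo <- make_topology(list(h = oligomer(strrep("A", 10), "h")))
  hairpin <- hb_frame(0, rbind(c(0, 9), c(1, 8), c(2, 7)))
  sf <- self_fold(hairpin, topo, "h")
  expect_equal(sf$longest_run, 3L)
  expect_equal(sf$loop_length, 4L)          # bases 3..6 unpaired
  expect_equal(sf$n_pairs, 3L)

  none <- self_fold(hb_frame(0), topo, "h")
  expect_equal(none$longest_run, 0L)
  expect_true(is.na(none$loop_length))

  tight <- self_fold(hb_frame(0, rbind(c(0, 2))), topo, "h", min_loop = 3)
  expect_equal(tight$n_pairs, 0L)           # separation 2 cannot close a loop
})

test_that("per-frame MCO never exceeds the pair's sequence-level omega", {
  cfg <- scenario_preset("p4p10", n_frames = 300, rng_seed = 6)
  sim <- generate_trajectory(cfg)
  tr <- pair_trace(sim$frames, sim$topology, "p4", "p10")
  expect_true(all(tr$tmo >= tr$mco))
  expect_lte(max(tr$mco), omega(cfg$oligos$p4, cfg$oligos$p10))
})
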