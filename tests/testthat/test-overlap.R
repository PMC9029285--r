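test_that("complementary implements Watson-Crick pairing only", {
  expect_true(complementary("A", "T"))
  expect_true(complementary("T", "A"))
  expect_true(complementary("G", "C"))
  expect_true(complementary("C", "G"))
  expect_false(complementary("A", "A"))
  expect_false(complementary("G", "T"))
  expect_false(complementary("A", "C"))
  expect_error(complementary("A", "X"), "X")
})

test_that("overlap_at scores single registers correctly", {
  # ACGT is its own reverse complement: a full 4-bp duplex at r = 0
  expect_equal(overlap_at("ACGT", "ACGT", 0), c(mco = 4L, tmo = 4L))
  # no canonical pair anywhere
  for (r in -3:3)
    expect_equal(overlap_at("AAAA", "GGGG", r), c(mco = 0L, tmo = 0L))
  # 11-mer vs 8-mer schematic: 3 opposing complementary pairs, 2 adjacent
  sp <- schematic_pair()
  expect_equal(overlap_at(sp$s1, sp$s2, 0), c(mco = 2L, tmo = 3L))
  expect_error(overlap_at("ACGT", "ACGT", 4), "outside admissible range")
  expect_error(overlap_at("ACGT", "ACGT", -4), "outside admissible range")
})

test_that("profile enumerates L + l - 1 positions, with mco <= tmo everywhere", {
  p <- overlap_profile(schematic_pair()$s1, schematic_pair()$s2)
  expect_length(p$mco_by_r, 18L)            # 11 + 8 - 1
  set.seed(21)
  for (i in 1:25) {
    L <- sample(1:40, 1); l <- sample(1:40, 1)
    pr <- overlap_profile(random_oligomer(L), random_oligomer(l))
    expect_length(pr$mco_by_r, L + l - 1L)
    expect_true(all(pr$tmo_by_r >= pr$mco_by_r))
    expect_identical(pr$omega, max(pr$mco_by_r))
  }
})

test_that("profile reproduces the printed predator/resource omegas", {
  oli <- builtin_oligomers()
  expect_identical(omega(oli$p4, oli$res), 4L)
  expect_identical(omega(oli$p10, oli$res), 10L)
  expect_identical(omega(oli$p4, oli$p10), 7L)
  expect_identical(omega(oli$p4, oli$p4), 8L)
  expect_identical(omega(oli$p10, oli$p10), 6L)
})

test_that("omega-windows are complementary, maximal and deterministically ordered", {
  oli <- builtin_oligomers()
  set.seed(33)
  cases <- c(list(list(oli$p4, oli$res), list(oli$p10, oli$res),
                  list(oli$p4, oli$p10)),
             replicate(15, list(random_oligomer(sample(8:40, 1)),
                                random_oligomer(sample(8:40, 1))),
                       simplify = FALSE))
  for (cs in cases) {
    pr <- overlap_profile(cs[[1]], cs[[2]])
    w <- pr$windows
    expect_identical(nrow(w) > 0, pr$omega >= 1L)
    if (nrow(w) > 1)
      expect_false(is.unsorted(order(w$r, w$start1)))
    a <- strsplit(cs[[1]]$seq, "")[[1]]; b <- strsplit(cs[[2]]$seq, "")[[1]]
    for (i in seq_len(nrow(w))) {
      expect_identical(w$length[i], pr$omega)
      for (k in seq_len(w$length[i]) - 1L) {
        expect_true(complementary(a[w$start1[i] + k + 1L],
                                  b[w$start2[i] + (w$length[i] - 1L) - k + 1L]))
      }
      # maximality: not extensible at either end within this register
      i0 <- w$start1[i]; i1 <- w$start1[i] + w$length[i] - 1L
      j1 <- w$start2[i]; j0 <- w$start2[i] + w$length[i] - 1L
      if (i0 > 0 && j0 < length(b) - 1L)
        expect_false(complementary(a[i0], b[j0 + 2L]))
      if (i1 < length(a) - 1L && j1 > 0)
        expect_false(complementary(a[i1 + 2L], b[j1]))
    }
  }
})

test_that("omega is symmetric and windows swap coordinates under argument swap", {
  set.seed(7)
  for (i in 1:20) {
    s1 <- random_oligomer(sample(5:35, 1)); s2 <- random_oligomer(sample(5:35, 1))
    p12 <- overlap_profile(s1, s2); p21 <- overlap_profile(s2, s1)
    expect_identical(p12$omega, p21$omega)
    if (nrow(p12$windows)) {
      k12 <- paste(p12$windows$start1, p12$windows$start2)
      k21 <- paste(p21$windows$start2, p21$windows$start1)
      expect_setequal(k12, k21)
    }
  }
})

test_that("omega of a strand against its reverse complement is the full length", {
  set.seed(12)
  for (len in c(1, 2, 7, 23, 60)) {
    s <- random_oligomer(len)
    expect_identical(omega(s, oligomer(revcomp(s), "rc")), as.integer(len))
  }
})

test_that("appending bases never decreases omega", {
  set.seed(18)
  for (i in 1:20) {
    s1 <- random_oligomer(sample(5:30, 1)); s2 <- random_oligomer(sample(5:30, 1))
    om <- omega(s1, s2)
    s1x <- oligomer(paste0(s1$seq, random_oligomer(sample(1:10, 1))$seq), "s1x")
    s2x <- oligomer(paste0(random_oligomer(sample(1:10, 1))$seq, s2$seq), "s2x")
    expect_gte(omega(s1x, s2), om)
    expect_gte(omega(s1, s2x), om)
    expect_gte(omega(s1x, s2x), om)
  }
})

test_that("profile omega agrees with the brute-force substring oracle", {
  oli <- builtin_oligomers()
  expect_identical(omega_oracle(oli$p10, oli$res), 10L)
  expect_identical(omega_oracle("ACGTACGT", "ACGTACGT"), 8L)
  expect_identical(omega_oracle("AAAA", "CCCC"), 0L)
  set.seed(5)
  for (i in 1:200) {
    s1 <- random_oligomer(sample(5:60, 1)); s2 <- random_oligomer(sample(5:60, 1))
    expect_identical(overlap_profile(s1, s2)$omega, as.integer(omega_oracle(s1, s2)))
  }
})

test_that("design_sequence hits the requested omega exactly and is seed-stable", {
  res <- builtin_oligomers()$res
  for (target in c(4L, 10L)) {
    d <- design_sequence(res, L = 50, omega_target = target, rng_seed = 7)
    expect_equal(d$length, 50L)
    expect_identical(as.integer(omega_oracle(d, res)), target)
    d2 <- design_sequence(res, L = 50, omega_target = target, rng_seed = 7)
    expect_identical(d$seq, d2$seq)
  }
  expect_error(design_sequence(res, L = 50, omega_target = 21, rng_seed = 1),
               "not achievable")
  expect_error(design_sequence(res, L = 10, omega_target = 11, rng_seed = 1),
               "not achievable")
})

test_that("profile export writes a readable per-position table", {
  oli <- builtin_oligomers()
  pr <- overlap_profile(oli$p4, oli$res)
  tf <- tempfile(fileext = ".tsv")
  export_profile(pr, tf)
  lines <- readLines(tf)
  expect_true(any(grepl("omega = 4", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 69L + nrow(pr$windows))   # 50 + 20 - 1 positions
  tj <- tempfile(fileext = ".json")
  export_profile(pr, tj, format = "json")
  parsed <- jsonlite::read_json(tj)
  expect_equal(parsed$omega, 4L)
  expect_length(parsed$windows, 2L)
})
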