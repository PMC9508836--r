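# Rule-based caller and hard filters: worked boundary cases plus an
# exhaustive truth-table comparison against a brute-force boolean oracle.

ev <- function(cd = 30, fd = 30, md = 30, ca = 15, fa = 0, ma = 0,
               af = NA_real_, q = NA_real_) {
  trio_evidence(c(child = cd, father = fd, mother = md),
                c(child = ca, father = fa, mother = ma),
                population_af = af, caller_quality = q)
}

test_that("VAF computation handles zero depth and rejects bad input", {
  expect_identical(compute_vaf(5, 10), 0.5)
  expect_identical(compute_vaf(0, 30), 0)
  expect_equal(compute_vaf(3, 7), 3 / 7)
  expect_identical(compute_vaf(0, 0), 0)
  expect_error(compute_vaf(5, 4), "alt_reads")
})

test_that("rule-based caller boundary semantics match the quoted clauses", {
  expect_true(inhouse_denovo_filter(ev(fa = 0, ma = 0))$pass)
  f <- inhouse_denovo_filter(ev(fd = 9))
  expect_false(f$pass)
  expect_identical(f$reason, "parental_coverage")
  expect_true(inhouse_denovo_filter(ev(fa = 2, fd = 20, ma = 0, md = 25))$pass)
  expect_false(inhouse_denovo_filter(ev(fa = 3, fd = 20))$pass)  # alt >= 3
  expect_false(inhouse_denovo_filter(ev(fa = 2, fd = 10))$pass)  # vaf 0.2
  expect_true(inhouse_denovo_filter(ev(fa = 2, fd = 20, ma = 2,
                                       md = 20))$pass)
})

test_that("rule-based caller matches a brute-force oracle exhaustively", {
  oracle <- function(fd, md, fa, ma) {
    fv <- if (fd == 0) 0 else fa / fd
    mv <- if (md == 0) 0 else ma / md
    (fd >= 10 && md >= 10) &&
      ((fa == 0 && ma == 0) ||
         (fv <= 0.15 && mv <= 0.15 && fa < 3 && ma < 3))
  }
  grid <- expand.grid(fd = 0:30, fa = 0:5, md = c(0, 9, 10, 25),
                      ma = c(0, 2, 3))
  grid <- grid[grid$fa <= grid$fd & grid$ma <= grid$md, ]
  got <- logical(nrow(grid))
  want <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got[i] <- inhouse_denovo_filter(
      ev(fd = g$fd, md = g$md, fa = g$fa, ma = g$ma))$pass
    want[i] <- oracle(g$fd, g$md, g$fa, g$ma)
  }
  expect_identical(got, want)
})

test_that("rule-based caller is monotone in parental evidence", {
  set.seed(3)
  for (i in 1:50) {
    fd <- sample(10:30, 1); md <- sample(10:30, 1)
    fa <- sample(0:4, 1); ma <- sample(0:4, 1)
    base <- inhouse_denovo_filter(ev(fd = fd, md = md, fa = fa, ma = ma))
    more_alt <- inhouse_denovo_filter(
      ev(fd = fd, md = md, fa = min(fa + 1, fd), ma = ma))
    # increasing parental alt reads never converts fail -> pass
    expect_false(!base$pass && more_alt$pass)
  }
})

test_that("population-AF pre-filter applies the WES/WGS presets", {
  expect_true(population_af_prefilter(ev(af = 0.009), "WES")$pass)
  expect_false(population_af_prefilter(ev(af = 0.01), "WES")$pass)
  expect_true(population_af_prefilter(ev(af = NA), "WES")$pass)
  expect_true(population_af_prefilter(ev(af = 5e-4, q = 16), "WGS")$pass)
  expect_false(population_af_prefilter(ev(af = 5e-4, q = 15), "WGS")$pass)
  expect_false(population_af_prefilter(ev(af = 1e-3, q = 16), "WGS")$pass)
})

test_that("high-quality filter enforces trio depth, child VAF and AF", {
  expect_true(high_quality_filter(ev(cd = 15, fd = 20, md = 25, ca = 7,
                                     af = 0))$pass)
  expect_false(high_quality_filter(ev(cd = 9, ca = 4))$pass)
  v <- high_quality_filter(ev(cd = 100, ca = 19))
  expect_false(v$pass)                       # vaf 0.19 < 20%
  expect_identical(v$reason, "child_vaf")
  expect_true(high_quality_filter(ev(cd = 100, ca = 20))$pass)
  expect_false(high_quality_filter(ev(af = 1e-4))$pass)  # strict <
  expect_true(high_quality_filter(ev(af = 0.99e-4))$pass)
})

test_that("evidence summarization counts CIGAR-consistent alt support", {
  ref <- synth_reference(2000L, seed = 9)
  for (vt in c("substitution", "insertion", "deletion")) {
    s <- simulate_site(sim_params(base_error_rate = 0,
                                  variant = list(type = vt, len = 2)),
                       reference = ref, seed = 33)
    e <- genotype_evidence(s$window)
    n_alt_sim <- sum(vapply(s$reads$child, function(r)
      grepl("I|D", r$cigar) ||
        substr(r$seq, s$site$position - r$pos0,
               s$site$position - r$pos0) != substr(s$site$ref, 1, 1),
      logical(1)))
    expect_identical(e$alt_reads[["child"]], n_alt_sim)
    expect_identical(e$alt_reads[["father"]], 0L)
    expect_identical(e$depth[["child"]], length(s$reads$child))
  }
})
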