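mk_calls <- function(ids, marker, call) {
  data.frame(individual = ids, marker = marker, call = call)
}

test_that("recombinants are phenotype-discordant dominant calls", {
  grp <- data.frame(id = 1:40,
                    group = rep(c("brown", "cream", "white"),
                                c(15, 10, 15)))
  concordant <- ifelse(grp$group == "white", "N", "P")
  r0 <- score_recombinants(mk_calls(1:40, "m1", concordant), grp)
  expect_equal(r0$recombinants, 0)
  expect_equal(r0$n_informative, 40)
  one_off <- concordant
  one_off[40] <- "P"                       # a white individual calling P
  r1 <- score_recombinants(mk_calls(1:40, "m1", one_off), grp)
  expect_equal(r1$recombinants, 1)
  # a cream individual calling N is also a recombinant (carrier, no band)
  one_cream <- concordant
  one_cream[16] <- "N"
  expect_equal(score_recombinants(mk_calls(1:40, "m1", one_cream),
                                  grp)$recombinants, 1)
  # missing calls are excluded from the informative count
  na_call <- concordant
  na_call[1] <- NA
  rna <- score_recombinants(mk_calls(1:40, "m1", na_call), grp)
  expect_equal(rna$n_informative, 39)
  expect_error(score_recombinants(mk_calls(41, "m1", "P"), grp),
               "no phenotype")
})

test_that("recombinant counts are order-invariant and grow with distance", {
  g <- small_genome(len = 40e6, cm = 80, causal = 10e6)
  cfg <- cross_config(n_f2 = 508L, seed = 55L)
  pop <- assign_phenotypes(simulate_f2(g, cfg))
  grp <- data.frame(id = seq_len(pop$n), group = pop$group)
  # 10 cM = 5 Mb here; Haldane r = (1 - exp(-0.2)) / 2 = 0.0906, and the
  # dominant-marker discordance probability is r - r^2/2 = 0.0865
  panel <- marker_panel(c("near", "mid", "far"), "chr1",
                        c(10.05e6, 15e6, 25e6))
  calls <- genotype_markers(pop, panel)
  rec <- score_recombinants(calls, grp)
  rec <- rec[match(panel$name, rec$marker), ]
  expect_true(all(diff(rec$recombinants) > 0))
  expected_mid <- 508 * 0.0865
  expect_lt(abs(rec$recombinants[2] - expected_mid),
            4 * sqrt(508 * 0.0865 * 0.9135))
  shuffled <- calls[sample(nrow(calls)), ]
  rec2 <- score_recombinants(shuffled, grp)
  expect_equal(rec2[match(panel$name, rec2$marker), "recombinants"],
               rec$recombinants)
})

test_that("the interval is delimited by the nearest recombinant flanks", {
  panel <- marker_panel(paste0("m", 1:4), "c1", c(10, 20, 30, 40) * 1e5)
  rec <- data.frame(marker = paste0("m", 1:4), recombinants = c(3, 1, 0, 2),
                    n_informative = 100)
  iv <- find_interval(panel, rec)
  expect_identical(iv$co_segregating, "m3")
  expect_identical(iv$left_marker, "m2")
  expect_identical(iv$right_marker, "m4")
  expect_equal(iv$span, 2e6)
  expect_false(iv$open)
})

test_that("degenerate panels are flagged open", {
  panel <- marker_panel(paste0("m", 1:3), "c1", c(1e5, 2e5, 3e5))
  all_zero <- data.frame(marker = paste0("m", 1:3), recombinants = 0,
                         n_informative = 10)
  iv <- find_interval(panel, all_zero)
  expect_true(iv$open)
  expect_identical(iv$left_marker, "m1")
  expect_identical(iv$right_marker, "m3")
  # no zero-recombinant marker: all tied minima reported, interval open
  none_zero <- data.frame(marker = paste0("m", 1:3),
                          recombinants = c(2, 1, 1), n_informative = 10)
  iv2 <- find_interval(panel, none_zero)
  expect_true(iv2$open)
  expect_identical(iv2$co_segregating, c("m2", "m3"))
  multi <- marker_panel(c("a", "b"), c("c1", "c2"), c(1, 2))
  expect_error(find_interval(multi, none_zero[1:2, ]), "single chromosome")
})

test_that("adding an interior marker never widens the interval", {
  g <- small_genome(len = 40e6, cm = 80, causal = 20e6)
  pop <- assign_phenotypes(simulate_f2(g, cross_config(n_f2 = 508L,
                                                       seed = 66L)))
  grp <- data.frame(id = seq_len(pop$n), group = pop$group)
  base_pos <- c(14e6, 17e6, 20.01e6, 23e6, 26e6)
  inner_pos <- sort(c(base_pos, 19e6, 21e6))
  span_of <- function(pos) {
    panel <- marker_panel(sprintf("p%02d", seq_along(pos)), "chr1", pos)
    rec <- score_recombinants(genotype_markers(pop, panel), grp)
    find_interval(panel, rec)$span
  }
  expect_lte(span_of(inner_pos), span_of(base_pos))
})

test_that("simulated interval mapping brackets the locus", {
  st <- interval_study(n_reps = 8, seed = 5L)
  expect_gte(mean(st$bracketed), 7 / 8)
})
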