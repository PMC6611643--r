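test_that("motif notation parses and formats round-trip", {
  m <- parse_motif("R-x-x-S/T-P")
  expect_equal(m$constraints, list(`-3` = "R", `1` = "P"))
  expect_equal(format_motif(m), "R-x-x-S/T-P")
  m2 <- parse_motif("S/T-D/E-x-D/E")
  expect_equal(m2$constraints, list(`1` = c("D", "E"), `3` = c("D", "E")))
  expect_error(parse_motif("R-x-x-P"), "no S/T centre")
  expect_error(motif_pattern(list()), ">= 1 constrained")
})

test_that("motif matching honours classes, x positions and padding", {
  stp <- parse_motif("S/T-P")
  expect_true(match_motif(stp, "AAAAAAASPAAAAAA"))
  expect_false(match_motif(stp, "AAAAAAASKAAAAAA"))

  rxxst <- parse_motif("R-x-x-S/T")
  expect_true(match_motif(rxxst, "AAAARAASAAAAAAA"))
  expect_false(match_motif(rxxst, "AAAAKAASAAAAAAA"))  # class is {R} only

  ## padding matches nothing
  expect_false(match_motif(stp, "AAAAAAAS_AAAAAA"))

  ## hand-counted toy set
  sites <- c("AAAARAASAAAAAAA",  # R at -3: match
             "AAAARAATPAAAAAA",  # R at -3: match
             "AAAAAAASAAAAAAA",  # no
             "RRRRRAAPAAAAAAA",  # centre P: not a valid site for R-x-x-S/T
             "AAAARTASAAAAAAA",  # R at -3: match
             "AAAAARASAAAAAAA")  # R at -2: no
  valid <- substr(sites, 8, 8) %in% c("S", "T")
  expect_equal(sum(match_motif(rxxst, sites[valid])), 3)
})

test_that("shuffled backgrounds preserve composition and link to sources", {
  ## all-identical flanks shuffle to themselves
  fore1 <- phosphosite_set("sp", "AAAAAAASAAAAAAA")
  bg1 <- generate_background(fore1, 10, seed = 1)
  expect_equal(length(bg1$sites), 10)
  expect_true(all(bg1$sites == fore1$sites))

  withr::with_seed(8, {
    fore <- phosphosite_set("sp", random_sites(500, 77))
    bg <- generate_background(fore, 10, seed = 2)
    expect_equal(length(bg$sites), 10 * length(fore$sites))
    expect_equal(attr(bg, "source")[11], 2L)
    ## per-site flank multiset conserved
    fm <- kinevo:::site_matrix(fore$sites)
    bm <- kinevo:::site_matrix(bg$sites)
    for (i in c(1, 250, 500)) {
      want <- sort(fm[i, c(1:7, 9:15)])
      for (k in 1:10)
        expect_equal(sort(bm[(i - 1) * 10 + k, c(1:7, 9:15)]), want)
    }
    ## pooled per-position frequencies mirror overall flank composition
    comp <- table(factor(fm[, c(1:7, 9:15)], levels = aa20))
    comp <- comp / sum(comp)
    for (col in c(2, 12)) {
      f <- table(factor(bm[, col], levels = aa20)) / nrow(bm)
      expect_lt(max(abs(as.numeric(f - comp))), 0.02)
    }
  })
})

test_that("superset binomial equals the exact tail and handles edge cases", {
  ## constructed counts: k=0 gives p-value 1
  fore <- phosphosite_set("sp", random_sites(100, 1))
  back <- generate_background(fore, 10, seed = 1)
  impossible <- motif_pattern(list(`1` = "W", `2` = "W", `3` = "W",
                                   `4` = "W", `5` = "W", `6` = "W"))
  res <- superset_binomial(impossible, fore, back)
  if (res$testable) expect_equal(res$p_value, 1)

  ## exact pmf-summation oracle over a (n, k, p0) grid
  tail_oracle <- function(k, n, p0)
    sum(vapply(k:n, function(j)
      choose(n, j) * p0^j * (1 - p0)^(n - j), 0))
  for (n in c(5, 10, 50)) for (p0 in c(0.05, 0.2, 0.9))
    for (k in unique(c(0, 1, floor(n / 2), n))) {
      expect_equal(stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
                   tail_oracle(max(k, 0), n, p0), tolerance = 1e-12)
    }

  ## p0 = 1 saturates the null
  expect_equal(stats::pbinom(10 - 1, 10, 1, lower.tail = FALSE), 1)

  ## worked enrichment: implanted +1 P against its S/T superset
  pp <- simulate_phosphoproteome("sp", 1000,
                                 motifs = list(parse_motif("S/T-P")),
                                 weights = 0.4, seed = 3)
  bg <- generate_background(pp, 10, seed = 4)
  stp <- parse_motif("S/T-P")
  r1 <- superset_binomial(stp, pp, bg)
  expect_lt(r1$p_value, 1e-6)
  expect_gt(r1$fold, 2)
  ## two-constraint motif conditions on its most frequent superset
  deep <- motif_pattern(list(`1` = "P", `3` = "W"))
  r2 <- superset_binomial(deep, pp, bg)
  expect_equal(format_motif(r2$superset), "S/T-P")
  expect_equal(r2$n, r1$k)  # foreground superset matches
})

test_that("monotonicity of the enrichment p-value in k and p0", {
  p_of <- function(k, n, p0) stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  n <- 40
  for (p0 in c(0.1, 0.5)) {
    pv <- vapply(0:n, p_of, 0, n = n, p0 = p0)
    expect_true(all(diff(pv) <= 1e-15))
  }
  for (k in c(5, 20)) {
    pv <- vapply(seq(0.05, 0.95, 0.05), function(p0) p_of(k, n, p0), 0)
    expect_true(all(diff(pv) >= -1e-15))
  }
})

test_that("greedy discovery finds implanted motifs and respects thresholds", {
  implant <- motif_pattern(list(`1` = "P", `3` = "K"))
  pp <- simulate_phosphoproteome("sp", 1500, motifs = list(implant),
                                 weights = 0.5, seed = 10)
  bg <- generate_background(pp, 10, seed = 11)
  found <- discover_motifs(pp, bg)
  keys <- vapply(found, function(f) format_motif(f$motif), "")
  expect_true("S/T-P-x-K" %in% keys)
  hit <- found[[match("S/T-P-x-K", keys)]]
  expect_gte(hit$n_fore, 20)
  expect_true(all(hit$step_p < 1e-6))

  ## min_occurrences above the foreground size: nothing emitted
  small <- phosphosite_set("sp", pp$sites[1:10])
  bg_small <- generate_background(small, 10, seed = 1)
  expect_length(discover_motifs(small, bg_small,
                                min_occurrences = 50), 0)
})

test_that("the cross-species filtering protocol applies every rule", {
  phyla <- data.frame(
    species = c(paste0("fun", 1:9), paste0("met", 1:6), paste0("pla", 1:3),
                paste0("exc", 1:3), "amo1", "het1"),
    superphylum = c(rep("fungi", 9), rep("metazoa", 6), rep("plants", 3),
                    rep("excavata", 3), "amoebozoa", "heterokonts"))
  disc <- rbind(
    ## S/T-P in 3 of 9 fungi (= 1/3): retained
    data.frame(species = paste0("fun", 1:3), motif = "S/T-P"),
    ## R-x-x-S/T in 2 of 9 fungi (< 1/3) and 1 metazoan: dropped
    data.frame(species = c("fun1", "fun2", "met1"), motif = "R-x-x-S/T"),
    ## K-x-x-S/T merges with R-x-x-S/T under R/K synonymy; together
    ## 2 fungi + 1 metazoan + 2 more fungi = 4 of 9 fungi: retained
    data.frame(species = c("fun3", "fun4"), motif = "K-x-x-S/T"),
    ## excavate motif in 2 of 3 excavates: retained
    data.frame(species = c("exc1", "exc2"), motif = "S/T-x-x-E-E"),
    ## amoebozoa/heterokont exclusive: dropped
    data.frame(species = c("amo1", "het1"), motif = "S/T-G-G"),
    ## S/T addition to classical S/T-P: dropped even though prevalent
    data.frame(species = paste0("met", 1:6), motif = "S/T-P-S"),
    ## D/E additions to the CK2 motif: dropped even though prevalent
    data.frame(species = paste0("met", 1:6), motif = "S/T-D-E-D"),
    ## the CK2 motif itself: retained
    data.frame(species = paste0("met", 1:6), motif = "S/T-E-x-D"))
  cat <- filter_motifs(disc, phyla)
  got <- sort(names(cat$retained))
  expect_equal(got, sort(c(
    format_motif(parse_motif("S/T-P")),
    format_motif(kinevo:::canonical_motif(parse_motif("R-x-x-S/T"))),
    format_motif(kinevo:::canonical_motif(parse_motif("S/T-x-x-E-E"))),
    format_motif(kinevo:::canonical_motif(parse_motif("S/T-E-x-D"))))))
  tab <- cat$motifs
  expect_true(tab$st_addition[tab$motif == "S/T-P-S"])
  ck2key <- format_motif(kinevo:::canonical_motif(parse_motif("S/T-D-E-D")))
  expect_true(tab$ck2_de_addition[tab$motif == ck2key])
  amok <- format_motif(parse_motif("S/T-G-G"))
  expect_false(tab$retained[tab$motif == amok])
  expect_error(filter_motifs(data.frame(species = "zz", motif = "S/T-P"),
                             phyla), "without superphylum")
})

test_that("coverage counts eligible motifs only, with the classic exceptions", {
  sites <- phosphosite_set("sp", c(
    "AAAAAAASPAAAAAA",   # S/T-P
    "AAAARAASAAAAAAA",   # R-x-x-S/T
    "AAAAAAASAKAAAAA",   # neither
    "GAAAAAASAAAAAAA",   # G at -7 (single-constraint motif, ineligible)
    "AAAAAAATPAAAAAA",   # S/T-P
    "AAAAAAATAAAAAAA"))
  ## catalog of only a single-constraint non-classic motif: coverage 0
  g_only <- list(motif_pattern(list(`-7` = "G")))
  expect_equal(as.numeric(phosphoproteome_coverage(g_only, sites)), 0)

  ## classic single-constraint exceptions count
  classics <- list(parse_motif("S/T-P"), parse_motif("R-x-x-S/T"))
  cov <- phosphoproteome_coverage(classics, sites)
  expect_equal(as.numeric(cov), 100 * 3 / 6)

  expect_error(phosphoproteome_coverage(classics,
                                        phosphosite_set("sp", character(0))),
               "empty")
})
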