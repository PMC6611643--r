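test_that("focal clade selection tolerates <15% spurious leaves, else descends", {
  ## monophyletic family of 12
  txt <- paste0("((", paste0("f", 1:12, ":1", collapse = ","), ")FC:1,(",
                paste0("o", 1:6, ":1", collapse = ","), ")OC:1)R;")
  tr <- tree_text(txt)
  labels <- toy_labels(tr$tip.label,
                       family = rep(c("F", "O"), c(12, 6)))
  cand <- select_focal_clade(tr, labels, "F", "family")
  expect_equal(cand$node, "FC")
  expect_equal(cand$purity, 1)
  expect_equal(cand$coverage, 1)

  ## 20-leaf clade with 2 spurious (10% < 15%): kept with purity 0.9
  txt2 <- paste0("((", paste0(c(paste0("f", 1:18), "x1", "x2"),
                              ":1", collapse = ","),
                 ")FC:1,(", paste0("o", 1:6, ":1", collapse = ","),
                 ")OC:1)R;")
  tr2 <- tree_text(txt2)
  lab2 <- toy_labels(tr2$tip.label,
                     family = c(rep("F", 18), "X", "X", rep("O", 6)))
  cand2 <- select_focal_clade(tr2, lab2, "F", "family")
  expect_equal(cand2$node, "FC")
  expect_equal(cand2$purity, 0.9)

  ## 10-leaf clade with 3 spurious (30%): largest pure subclade instead
  txt3 <- paste0("(((f1:1,f2:1,f3:1,f4:1,f5:1,f6:1)P:1,",
                 "(f7:1,x1:1,x2:1,x3:1)Q:1)FC:1,",
                 "(o1:1,o2:1,o3:1,o4:1,o5:1)OC:1)R;")
  tr3 <- tree_text(txt3)
  lab3 <- toy_labels(tr3$tip.label,
                     family = c(rep("F", 7), "X", "X", "X", rep("O", 5)))
  cand3 <- select_focal_clade(tr3, lab3, "F", "family")
  expect_equal(cand3$node, "P")   # 6 pure > any tolerated mixed clade
  expect_equal(cand3$purity, 1)
  expect_equal(cand3$coverage, 6 / 7)
})

test_that("sister selection enforces size and shared parent category", {
  txt <- paste0("(((f", paste0(1:6, ":1", collapse = ",f"), ")FC:1,",
                "(s1:1,s2:1,s3:1,s4:1,s5:1,s6:1,s7:1)SC:1)I:1,",
                "(z1:1,z2:1)Z:1)R;")
  tr <- tree_text(txt)
  lab <- toy_labels(tr$tip.label,
                    family = c(rep("F", 6), rep("S", 7), "Z", "Z"))
  lab$subfamily <- lab$family
  lab$group <- "G1"
  ## subfamily level: sister of 7 leaves, same (single) family? Here the
  ## dominant family labels differ, so make them share one family first.
  lab$family <- "FAM"
  cand <- select_focal_clade(tr, lab, "F", "subfamily")
  cmp <- select_sister_clade(tr, cand, lab)
  expect_true(cmp$scorable)
  expect_equal(cmp$sister_node, "SC")
  expect_equal(cmp$ancestor_A, "FC")
  expect_equal(cmp$ancestor_B, "SC")

  ## sister of size < 5 is unscorable
  txt2 <- paste0("((f", paste0(1:6, ":1", collapse = ",f"), ")FC:1,",
                 "(s1:1,s2:1,s3:1)SC:1)R;")
  tr2 <- tree_text(txt2)
  lab2 <- toy_labels(tr2$tip.label, family = "FAM",
                     subfamily = c(rep("F", 6), rep("S", 3)))
  cmp2 <- select_sister_clade(
    tr2, select_focal_clade(tr2, lab2, "F", "subfamily"), lab2)
  expect_false(cmp2$scorable)
  expect_match(cmp2$reason, "5 or more")

  ## subfamily sister dominated by a different family is unscorable
  lab3 <- lab
  lab3$family <- c(rep("FAM1", 6), rep("FAM2", 7), "FAMZ", "FAMZ")
  cmp3 <- select_sister_clade(
    tr, select_focal_clade(tr, lab3, "F", "subfamily"), lab3)
  expect_false(cmp3$scorable)
  expect_match(cmp3$reason, "different family")
})

test_that("recent conservation follows the rescaled BLOSUM62 arithmetic", {
  B <- kinevo:::rescaled_blosum62()
  ## identical tryptophans: W-W is the matrix maximum -> RC = 1
  expect_equal(recent_conservation(rep("W", 5)), 1)
  ## {R,R,E,E}: mean of 6 rescaled pairs
  expected <- (B["R", "R"] + 4 * B["R", "E"] + B["E", "E"]) / 6
  expect_equal(recent_conservation(c("R", "R", "E", "E")), expected,
               tolerance = 1e-12)
  ## gaps contribute zero but stay in the denominator
  expect_equal(recent_conservation(c("W", "W", "-")),
               B["W", "W"] / 3, tolerance = 1e-12)
  ## fewer than two residues: undefined
  expect_true(is.na(recent_conservation(c("W", "-", "-"))))
})

test_that("ancestral agreement follows the matching/mismatching rules", {
  post <- stats::setNames(rep(0, 20), aa20)
  post["R"] <- 0.97; post["K"] <- 0.03
  ag <- ancestral_agreement("R", "R", post)
  expect_equal(ag$AC, 1)
  expect_equal(ag$p_AC, 0.97)

  post2 <- stats::setNames(rep(0, 20), aa20)
  post2["E"] <- 0.98; post2["R"] <- 0.02
  ag2 <- ancestral_agreement("R", "E", post2)
  expect_equal(ag2$AC, -1)
  expect_equal(ag2$p_AC, 0.98)

  ## contradictory table: differing residues but all mass on A's residue
  post3 <- stats::setNames(rep(0, 20), aa20)
  post3["R"] <- 1
  ag3 <- ancestral_agreement("R", "E", post3)
  expect_equal(ag3$AC, -1)
  expect_equal(ag3$p_AC, 0)

  ## ancestral gap never matches a residue
  ag4 <- ancestral_agreement("-", "R", post3)
  expect_equal(ag4$AC, -1)
})

test_that("divergence scores recompose exactly and match a straight-line oracle", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- 6
      seqs <- stats::setNames(vapply(1:(2 * n), function(i)
        paste(sample(c(aa20, "-"), 50, TRUE,
                     prob = c(rep(0.045, 20), 0.1)), collapse = ""), ""),
        c(paste0("a", 1:n), paste0("b", 1:n)))
      txt <- paste0("((", paste0("a", 1:n, ":1", collapse = ","), ")CA:1,(",
                    paste0("b", 1:n, ":1", collapse = ","), ")CB:1)R;")
      tr <- tree_text(txt)
      lab <- toy_labels(names(seqs),
                        family = rep(c("A", "B"), each = n))
      aln <- kinase_alignment(seqs, lab)
      post <- lapply(c(CA = 1, CB = 2, R = 3), function(i) {
        g <- matrix(stats::rgamma(20 * 50, 0.3), 20, 50,
                    dimnames = list(aa20, NULL))
        sweep(g, 2, colSums(g), "/")
      })
      anc <- ancestral_states(post)
      cmp <- select_sister_clade(
        tr, select_focal_clade(tr, lab, "A", "family"), lab)
      sc <- divergence_scores(cmp, aln, anc)

      ## independent straight-line recomputation
      B <- kinevo:::rescaled_blosum62()
      for (k in seq_len(nrow(sc))) {
        j <- sc$column[k]
        col <- aln$mat[paste0("a", 1:n), j]
        res <- col[col != "-"]
        tot <- 0
        for (u in seq_along(col)) for (v in seq_len(u - 1)) {
          if (col[u] != "-" && col[v] != "-")
            tot <- tot + B[col[u], col[v]]
        }
        rc <- tot / choose(length(col), 2)
        ra <- anc$state$CA[j]; rb <- anc$state$CB[j]
        pB <- anc$post$CB[, j]
        if (ra == rb) { ac <- 1; p <- pB[rb] } else {
          ac <- -1; p <- 1 - pB[ra]
        }
        s_oracle <- rc - ac * p
        expect_equal(sc$S[k], unname(s_oracle), tolerance = 1e-12)
        expect_equal(sc$S[k], sc$RC[k] - sc$AC[k] * sc$p_AC[k],
                     tolerance = 1e-15)
      }
      expect_true(all(sc$S >= -1 & sc$S <= 2))
    }
  })
})

test_that("forced-arithmetic scores hit the documented extremes", {
  ## RC=1, AC=+1, p=1 -> S=0; RC=1, AC=-1, p=1 -> S=2
  post <- stats::setNames(rep(0, 20), aa20); post["W"] <- 1
  agree <- ancestral_agreement("W", "W", post)
  expect_equal(1 - agree$AC * agree$p_AC, 0)
  postE <- stats::setNames(rep(0, 20), aa20); postE["E"] <- 1
  differ <- ancestral_agreement("W", "E", postE)
  expect_equal(1 - differ$AC * differ$p_AC, 2)
})

test_that("switch calling uses interpolated percentiles with strict exceedance", {
  mk_table <- function(S, anc_a, anc_b, focal = "F") {
    tb <- data.frame(column = seq_along(S),
                     domain_position = seq_along(S),
                     RC = NA_real_, AC = NA_real_, p_AC = NA_real_, S = S)
    attr(tb, "comparison") <- list(focal = focal, ancestor_A = anc_a,
                                   ancestor_B = anc_b)
    class(tb) <- c("divergence_scores", class(tb))
    tb
  }
  ## 100 pooled scores 1..100: threshold 95.05, switches at 96..100
  tb <- mk_table(1:100, "n1", "n2")
  prof <- call_switches(list(tb), "family", n_positions = 100)
  expect_equal(prof$threshold, 95.05)
  expect_equal(sum(prof$counts), 5)
  expect_equal(as.integer(names(prof$counts)[prof$counts > 0]), 96:100)

  ## all scores equal: nothing strictly above the percentile
  prof0 <- call_switches(list(mk_table(rep(1, 50), "n1", "n2")), "family",
                         n_positions = 50)
  expect_equal(sum(prof0$counts), 0)

  ## duplicate ancestral pairs collapse to one comparison
  dup <- list(mk_table(1:100, "n1", "n2"),
              mk_table(1:100, "n2", "n1", focal = "F2"))
  prof2 <- call_switches(dup, "family", n_positions = 100)
  expect_equal(prof2$counts, prof$counts)
  ## and concatenating a table with itself changes no count
  prof3 <- call_switches(c(list(tb), list(tb)), "family",
                         n_positions = 100)
  expect_equal(prof3$counts, prof$counts)
})

test_that("frequently switching positions strictly exceed the 90th percentile", {
  counts <- stats::setNames(integer(246), 1:246)
  prof <- structure(list(level = "family", threshold = 0, counts = counts),
                    class = "switch_profile")
  expect_length(frequently_switching(prof), 0)

  ## toy 10-position profile: counts 1..10, 90th percentile = 9.1
  prof2 <- structure(list(level = "family", threshold = 0,
                          counts = stats::setNames(1:10, 1:10)),
                     class = "switch_profile")
  expect_equal(frequently_switching(prof2), 10L)
})

test_that("category tests reproduce exact hypergeometric and null MW results", {
  ## 2x2 table (3,1;1,5): one-sided Fisher p = 25/210
  counts <- stats::setNames(c(5, 6, 7, 9, 0, 1, 0, 0, 0, 2), 1:10)
  cats <- c(rep("catalytic", 4), rep("other", 6))
  names(cats) <- 1:10
  prof <- structure(list(level = "family", threshold = 0, counts = counts),
                    class = "switch_profile")
  res <- category_tests(prof, frequent = c(1, 2, 3, 5), cats,
                        mw_category = "catalytic")
  expect_equal(res$fisher$table["frequent", "named_category"], 3)
  expect_equal(res$fisher$p, 25 / 210, tolerance = 1e-12)

  ## identical count distributions: one-tailed MW p = 0.5
  counts2 <- stats::setNames(c(1, 2, 3, 4, 1, 2, 3, 4), 1:8)
  cats2 <- stats::setNames(rep(c("proximal", "other"), each = 4), 1:8)
  prof2 <- structure(list(level = "family", threshold = 0,
                          counts = counts2),
                     class = "switch_profile")
  res2 <- category_tests(prof2, frequent = integer(0), cats2)
  expect_equal(res2$mann_whitney$p, 0.5, tolerance = 1e-12)
})
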