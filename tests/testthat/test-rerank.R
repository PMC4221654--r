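# Class table helper: pair frequency table with chosen fp values, 0 elsewhere.
class_tab <- function(...) {
  vals <- list(...)
  tab <- contactprop:::all_unordered_pairs()
  tab$Jc <- 0L
  tab$fp <- 0
  for (k in names(vals)) {
    a <- strsplit(k, ":")[[1]]
    tab$fp[tab$aa1 == min(a) & tab$aa2 == max(a)] <- vals[[k]]
  }
  class(tab) <- c("PairFrequencyTable", "data.frame")
  tab
}

test_that("top-set pair frequencies count the candidate per the flags", {
  top <- list(c("A", "L"), c("L", "A"))
  expect_equal(compute_domain_pair_fp(top, c("A", "L"), 200, include = TRUE),
               0.01)
  expect_equal(compute_domain_pair_fp(top, c("A", "L"), 200, include = FALSE),
               0.005)
  expect_equal(compute_domain_pair_fp(list(), c("A", "L"), 200,
                                      include = FALSE), 0)
  expect_error(compute_domain_pair_fp(top, c("A", "X"), 200), "never")

  # candidate outside the top set (addition pass semantics)
  expect_equal(compute_domain_pair_fp(top, c("A", "L"), 200, include = TRUE,
                                      candidate_in_top = FALSE), 3 / 200)

  # brute-force tally on a random top set
  set.seed(5)
  types <- replicate(30, sort(sample(aa_standard, 2)), simplify = FALSE)
  pair <- c("L", "V")
  want <- sum(vapply(types, function(p)
    identical(p, sort(pair)), logical(1)))
  expect_equal(compute_domain_pair_fp(types, pair, 50, include = TRUE,
                                      candidate_in_top = FALSE),
               (want + 1) / 50)
})

test_that("normalized top-set frequencies divide by frequency products", {
  f <- c(A = 0.5, L = 0.5)
  top <- list(c("A", "L"))
  expect_equal(compute_domain_pair_fpn(top, c("A", "L"), 200, f,
                                       include = TRUE), (1 / 200) / 0.25)
  expect_equal(compute_domain_pair_fpn(list(), c("A", "L"), 200, f,
                                       include = FALSE), 0)
  expect_error(compute_domain_pair_fpn(top, c("A", "V"), 200, f), "zero")
})

test_that("re-ranking follows the hand-executed trace on a 6-pair instance", {
  aa <- c("A", "A", "A", "L", "L", "L")
  sc <- data.frame(i = c(1, 4, 1, 4, 2, 5), j = c(2, 5, 3, 6, 3, 6),
                   score = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))

  # class favouring Ala-Ala: the L:L pair in the top set is removed, the
  # next A:A pair from the rest set is added
  out <- rerank(sc, aa, class_tab(`A:A` = 1.0), mode = "fp", K = 3)
  expect_equal(out$i, c(1, 1, 2))
  expect_equal(out$j, c(2, 3, 3))
  expect_equal(out$status, c("kept", "kept", "added"))

  # all-zero class table: every top pair is removed, nothing is addable,
  # and backfill restores the original top set latest-removed-first
  out0 <- rerank(sc, aa, class_tab(), mode = "fp", K = 3)
  expect_equal(out0$i, c(1, 4, 1))
  expect_equal(out0$j, c(2, 5, 3))
  expect_equal(out0$status, rep("backfilled", 3))
})

test_that("a domain with exactly K pairs conserves the pair set", {
  dom <- make_hairpin(10, seed = 8)
  tm <- truth_map(dom)
  sc <- make_scores(tm, seed = 8)
  sc <- sc[1:40, ]
  fp_tab <- class_tab(`L:L` = 0.5, `V:V` = 0.5)
  out <- rerank(sc, dom, fp_tab, mode = "fp", K = 40)
  expect_equal(sort(paste(out$i, out$j)), sort(paste(sc$i, sc$j)))

  # K above the pair count: full input with a warning
  expect_warning(big <- rerank(sc, dom, fp_tab, mode = "fp", K = 100),
                 "exceeds")
  expect_equal(nrow(big), 40L)
})

test_that("pairs containing X are inert", {
  aa <- c("X", "A", "X", "A", "X", "L")
  sc <- data.frame(i = c(1, 3, 5, 2), j = c(2, 4, 6, 4),
                   score = c(0.9, 0.8, 0.7, 0.6))
  out <- rerank(sc, aa, class_tab(`A:A` = 1), mode = "fp", K = 3)
  # the three X pairs stay exactly where they were
  expect_equal(out$i[1:3], c(1, 3, 5))
  expect_equal(out$status[1:3], rep("kept", 3))
})

test_that("random instances match the independent transcription oracle", {
  set.seed(99)
  for (trial in 1:60) {
    n <- sample(8:16, 1)
    aa <- sample(c("A", "L", "V", "G", "X"), n, replace = TRUE,
                 prob = c(0.3, 0.3, 0.2, 0.15, 0.05))
    npairs <- sample(5:25, 1)
    all_ij <- t(combn(n, 2))
    pick <- all_ij[sample(nrow(all_ij), min(npairs, nrow(all_ij))), ,
                   drop = FALSE]
    sc <- data.frame(i = pick[, 1], j = pick[, 2],
                     score = round(runif(nrow(pick)), 2))
    K <- sample(3:10, 1)
    tabs <- class_tab(`A:A` = 0.3, `A:L` = 0.25, `L:L` = 0.2, `L:V` = 0.15,
                      `V:V` = 0.1)
    out <- suppressWarnings(rerank(sc, aa, tabs, mode = "fp", K = K))
    cls_vals <- setNames(tabs$fp, paste(tabs$aa1, tabs$aa2, sep = ":"))
    orc <- oracle_rerank(sc, aa, cls_vals, K, mode = "fp")
    expect_equal(nrow(out), min(K, nrow(sc)))
    expect_setequal(paste(out$i, out$j), paste(orc$i, orc$j))
    # deterministic on replay
    out2 <- suppressWarnings(rerank(sc, aa, tabs, mode = "fp", K = K))
    expect_identical(out, out2)
  }
})

test_that("fpn mode matches the oracle with domain frequencies", {
  set.seed(123)
  for (trial in 1:20) {
    n <- 12
    aa <- sample(c("A", "L", "V"), n, replace = TRUE)
    all_ij <- t(combn(n, 2))
    pick <- all_ij[sample(nrow(all_ij), 20), , drop = FALSE]
    sc <- data.frame(i = pick[, 1], j = pick[, 2], score = runif(20))
    tabs <- class_tab(`A:A` = 0.4, `A:L` = 0.3, `L:V` = 0.3)
    tabs$fpn <- tabs$fp * 9  # arbitrary but fixed normalized values
    K <- 6
    out <- rerank(sc, aa, tabs, mode = "fpn", K = K)
    f_ad <- table(factor(aa, levels = aa_standard)) / n
    f_ad <- setNames(as.numeric(f_ad), aa_standard)
    cls_vals <- setNames(tabs$fpn, paste(tabs$aa1, tabs$aa2, sep = ":"))
    orc <- oracle_rerank(sc, aa, cls_vals, K, mode = "fpn", f_ad = f_ad)
    expect_setequal(paste(out$i, out$j), paste(orc$i, orc$j))
  }
})

test_that("a class table equal to the top set's own distribution is a fixed point", {
  aa <- c("A", "A", "L", "L", "V", "V", "A", "L")
  sc <- data.frame(i = c(1, 3, 5, 1, 2), j = c(2, 4, 6, 7, 8),
                   score = c(0.9, 0.8, 0.7, 0.3, 0.2))
  K <- 3  # top set: A:A, L:L, V:V -> empirical fp 1/3 each
  tabs <- class_tab(`A:A` = 1 / 3, `L:L` = 1 / 3, `V:V` = 1 / 3)
  out <- rerank(sc, aa, tabs, mode = "fp", K = K)
  expect_equal(out$status, rep("kept", 3))
  expect_equal(out$i, c(1, 3, 5))
})
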