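# Ensemble reused across the statistic tests.
prop_domains <- random_domains(12, seed0 = 21)
prop_maps <- lapply(prop_domains, function(d)
  build_contact_map(d, contact_params(8, 5)))
prop_sums <- Map(summarize_domain, prop_domains, prop_maps)

test_that("domain summaries count contact-forming and total residues", {
  # AALL with only the (1,4) pair in contact
  dom <- toy_domain(rep(0, 12), c("A", "A", "L", "L"))
  dom$cbeta <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0), c(3, 0, 0))
  map <- build_contact_map(dom, contact_params(8, 2))
  expect_equal(unname(map$pairs), matrix(c(1L, 4L), 1))
  s <- summarize_domain(dom, map)
  expect_equal(s$Ic[["A"]], 1L); expect_equal(s$Iw[["A"]], 2L)
  expect_equal(s$Ic[["L"]], 1L); expect_equal(s$Iw[["L"]], 2L)

  # contact-free domain
  far <- toy_domain(rep(0, 9), c("A", "C", "X"), id = "far")
  far$cbeta <- cbind(c(0, 500, 1000), 0, 0)
  s0 <- summarize_domain(far, build_contact_map(far, contact_params(8, 1)))
  expect_true(all(s0$Ic == 0L))
  expect_equal(s0$Iw[["X"]], 1L)

  expect_error(summarize_domain(dom, build_contact_map(far, contact_params(8, 1))),
               "built from domain")

  # brute-force recount on a random domain
  d <- prop_domains[[1]]; m <- prop_maps[[1]]; s <- prop_sums[[1]]
  touched <- unique(c(brute_contacts(d, 8, 5)))
  for (a in c("A", "L", "V", "G")) {
    expect_equal(s$Ic[[a]], sum(d$aa[touched] == a))
    expect_equal(s$Iw[[a]], sum(d$aa == a))
  }
})

test_that("Wc is the unweighted mean of per-protein contact ratios", {
  mk <- function(Ic, Iw, id) structure(
    list(domain_id = id, class_label = "alpha", topology_label = "t",
         Ic = Ic, Iw = Iw), class = "DomainContactSummary")
  zeros <- setNames(rep(0L, 21), aa_extended)
  s1 <- mk(`[<-`(zeros, "A", 2L), `[<-`(zeros, "A", 2L), "p1")  # all Ala touch
  wc1 <- compute_Wc(list(s1))
  expect_equal(wc1$Wc[wc1$aa == "A"], 1)
  expect_true(is.na(wc1$Wc[wc1$aa == "L"]))  # absent type: undefined, not 0
  expect_equal(wc1$N[wc1$aa == "L"], 0L)

  s2 <- mk(`[<-`(zeros, "A", 1L), `[<-`(zeros, "A", 2L), "p2")  # ratio 0.5
  wc <- compute_Wc(list(s1, s2))
  expect_equal(wc$Wc[wc$aa == "A"], 0.75)
  expect_equal(wc$N[wc$aa == "A"], 2L)
  expect_equal(wc$sd[wc$aa == "A"], sd(c(1, 0.5)))

  # brute-force equality on the synthetic ensemble
  wc_all <- compute_Wc(prop_sums)
  for (a in aa_standard) {
    expect_equal(wc_all$Wc[wc_all$aa == a],
                 oracle_W(prop_domains, prop_maps, a), tolerance = 1e-12)
  }
  expect_true(all(wc_all$Wc >= 0 & wc_all$Wc <= 1, na.rm = TRUE))
})

test_that("Wt equals Wc when the topology is the whole class", {
  wt <- compute_Wt(prop_sums)
  wc <- compute_Wc(prop_sums)
  expect_equal(wt$Wt, wc$Wc)
  # single-protein topology: Wt is that protein's ratios
  wt1 <- compute_Wt(prop_sums[1])
  s <- prop_sums[[1]]
  for (a in aa_standard[s$Iw[aa_standard] > 0]) {
    expect_equal(wt1$Wt[wt1$aa == a], s$Ic[[a]] / s$Iw[[a]])
  }
})

test_that("fp tallies unordered pair contacts over the class total", {
  dom <- toy_domain(rep(0, 12), c("A", "X", "X", "L"))
  dom$cbeta <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0), c(3, 0, 0))
  map <- build_contact_map(dom, contact_params(8, 2))
  fp <- compute_fp(list(map), list(dom), "alpha")
  expect_equal(fp$fp[fp$aa1 == "A" & fp$aa2 == "L"], 1)
  expect_equal(sum(fp$fp), 1)
  expect_equal(attr(fp, "Jw"), 1L)

  # Ala-Leu and Cys-Cys -> 0.5 each; homotypic contacts counted once
  dom2 <- toy_domain(rep(0, 12), c("C", "A", "C", "L"))
  dom2$cbeta <- rbind(c(0, 0, 0), c(100, 0, 0), c(3, 0, 0), c(103, 0, 0))
  map2 <- build_contact_map(dom2, contact_params(8, 2))
  fp2 <- compute_fp(list(map2), list(dom2), "alpha")
  expect_equal(fp2$fp[fp2$aa1 == "C" & fp2$aa2 == "C"], 0.5)
  expect_equal(fp2$fp[fp2$aa1 == "A" & fp2$aa2 == "L"], 0.5)

  # class of domains at the 8 A / separation 10 setting: sums to 1 and
  # matches the brute-force tally
  doms <- lapply(1:10, function(s) make_hairpin(12, seed = 300 + s,
                                                x_rate = 0.05))
  maps <- lapply(doms, truth_map)
  fpc <- compute_fp(maps, doms, "beta")
  expect_equal(sum(fpc$fp), 1, tolerance = 1e-12)
  for (pr in list(c("L", "V"), c("C", "C"), c("I", "L"), c("F", "X"))) {
    expect_equal(fpc$fp[fpc$aa1 == min(pr) & fpc$aa2 == max(pr)],
                 oracle_fp(doms, maps, pr[1], pr[2]), tolerance = 1e-12)
  }
  # alternative total excluding X pairs
  fpx <- compute_fp(maps, doms, "beta", include_x_in_total = FALSE)
  expect_equal(fpx$fp[fpx$aa1 == "I" & fpx$aa2 == "L"],
               oracle_fp(doms, maps, "I", "L", include_x_in_total = FALSE),
               tolerance = 1e-12)

  # empty class: undefined with warning
  empty <- make_helix(12, seed = 1)
  expect_warning(
    fpe <- compute_fp(list(truth_map(empty)), list(empty), "alpha"),
    "undefined")
  expect_true(all(is.na(fpe$fp)))
})

test_that("fpn divides by occurrence frequency products", {
  fp <- compute_fp(prop_maps, prop_domains, "alpha")
  freqs <- compute_frequencies(prop_domains)
  fpn <- compute_fpn(fp, freqs)
  nonx <- fpn$aa1 != "X" & fpn$aa2 != "X"
  expect_equal(fpn$fpn[nonx],
               fpn$fp[nonx] / (freqs[fpn$aa1[nonx]] * freqs[fpn$aa2[nonx]]),
               ignore_attr = TRUE)
  expect_true(all(is.na(fpn$fpn[!nonx])))

  # hand value: fp 0.5 with frequencies 0.5 each -> 2.0
  tab <- fp[1, ]; tab$aa1 <- "A"; tab$aa2 <- "L"; tab$fp <- 0.5
  f <- setNames(rep(0, 20), aa_standard); f[c("A", "L")] <- 0.5
  expect_equal(compute_fpn(tab, f)$fpn, 2.0)

  # inconsistent inputs: positive fp with zero frequency
  f2 <- f; f2["L"] <- 0
  expect_error(compute_fpn(tab, f2), "zero occurrence frequency")
})

test_that("occurrence frequencies exclude X and sum to one", {
  dom <- toy_domain(rep(0, 12), c("A", "A", "A", "L"))
  fr <- compute_frequencies(list(dom))
  expect_equal(fr[["A"]], 0.75)
  expect_equal(fr[["L"]], 0.25)

  xdom <- toy_domain(rep(0, 6), c("X", "X"))
  expect_error(compute_frequencies(list(xdom)), "no standard amino acids")

  expect_equal(sum(compute_frequencies(prop_domains)), 1, tolerance = 1e-12)
})

test_that("St measures topology-class divergence of contact propensities", {
  wc <- compute_Wc(prop_sums)
  wt <- compute_Wt(prop_sums)
  expect_equal(compute_St(wt, wc)$St, 0)  # topology == class

  # hand arithmetic: two types differing by 0.1 each
  mkw <- function(vals, col) {
    out <- data.frame(aa = aa_standard, W = NA_real_, sd = NA_real_, N = 0L)
    names(out)[2] <- col
    for (a in names(vals)) {
      out[[col]][out$aa == a] <- vals[[a]]
      out$N[out$aa == a] <- 3L
    }
    out
  }
  wt2 <- mkw(c(A = 0.6, L = 0.3), "Wt")
  wc2 <- mkw(c(A = 0.5, L = 0.2), "Wc")
  expect_equal(compute_St(wt2, wc2)$St, sqrt(0.02 / 1))

  # random tables vs direct transcription
  set.seed(77)
  vals_t <- runif(20); vals_c <- runif(20)
  wt3 <- mkw(setNames(vals_t, aa_standard), "Wt")
  wc3 <- mkw(setNames(vals_c, aa_standard), "Wc")
  expect_equal(compute_St(wt3, wc3)$St,
               oracle_St(vals_t, vals_c, rep(TRUE, 20)), tolerance = 1e-12)

  # fewer than two types: undefined
  wt4 <- mkw(c(A = 0.5), "Wt")
  expect_warning(res <- compute_St(wt4, mkw(c(A = 0.4), "Wc")), "fewer than 2")
  expect_true(is.na(res$St))
})

test_that("Wc responds monotonically to the contact definition", {
  doms <- prop_domains
  wc_of <- function(cutoff, sep) {
    maps <- lapply(doms, function(d)
      build_contact_map(d, contact_params(cutoff, sep)))
    compute_Wc(Map(summarize_domain, doms, maps))$Wc
  }
  lo <- wc_of(6, 5); hi <- wc_of(10, 5)
  expect_true(all(hi - lo >= -1e-12, na.rm = TRUE))
  near <- wc_of(8, 3); far <- wc_of(8, 9)
  expect_true(all(near - far >= -1e-12, na.rm = TRUE))
})
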