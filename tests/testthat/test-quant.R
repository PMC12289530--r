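mk_assign <- function(peptide, acc, unique = TRUE) {
  data.frame(peptide = peptide, accessions = acc,
             n_accessions = ifelse(acc == "", 0L, 1L),
             unique = unique, unassigned = acc == "",
             stringsAsFactors = FALSE)
}

test_that("aggregate_proteins sums unique peptides and applies class rules", {
  tab <- data.frame(
    peptide = c("AAAAAAK", "CCCCCCK", "DDDDDDK", "EEEEEEK"),
    s1 = c(3, 5, 10, 7), s2 = c(1, 2, NA, 4),
    stringsAsFactors = FALSE
  )
  assign <- mk_assign(tab$peptide, c("P1", "P1", "M1", "P2"))
  classes <- c(P1 = "canonical", M1 = "microprotein", P2 = "canonical")
  q <- aggregate_proteins(tab, assign, classes, c("s1", "s2"))
  # canonical with two unique peptides: kept, intensities summed
  expect_equal(q$s1[q$protein_id == "P1"], 8)
  expect_equal(q$s2[q$protein_id == "P1"], 3)
  # microprotein with one unique peptide: kept; missing stays missing
  expect_equal(q$s1[q$protein_id == "M1"], 10)
  expect_true(is.na(q$s2[q$protein_id == "M1"]))
  # canonical with one unique peptide: dropped
  expect_false("P2" %in% q$protein_id)
  expect_equal(attr(q, "dropped"), "P2")
  # non-unique peptides contribute nothing
  assign2 <- mk_assign(tab$peptide, c("P1", "P1", "M1", "P2"),
                       unique = c(TRUE, TRUE, FALSE, TRUE))
  q2 <- aggregate_proteins(tab, assign2, classes, c("s1", "s2"))
  expect_false("M1" %in% q2$protein_id)
})

test_that("log2_fold_change averages observed intensities", {
  x <- c(a1 = 4, a2 = 4, b1 = 2, b2 = 2)
  expect_equal(log2_fold_change(x, c("a1", "a2"), c("b1", "b2")), 1)
  expect_equal(log2_fold_change(x, c("a1", "a2"), c("a1", "a2")), 0)
  y <- c(a1 = 10, a2 = NA, b1 = NA, b2 = NA)
  expect_true(is.na(log2_fold_change(y, c("a1", "a2"), c("b1", "b2"))))
  set.seed(51)
  for (k in 1:20) {
    v <- setNames(runif(6, 1, 100), paste0("s", 1:6))
    v[sample(6, sample(0:2, 1))] <- NA
    ga <- paste0("s", 1:3); gb <- paste0("s", 4:6)
    got <- log2_fold_change(v, ga, gb)
    ma <- mean(v[ga], na.rm = TRUE); mb <- mean(v[gb], na.rm = TRUE)
    want <- if (is.nan(ma) || is.nan(mb)) NA_real_ else log2(ma / mb)
    expect_equal(got, want)
  }
})

test_that("bh_adjust reproduces the closed-form step-up exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "sorfpipe_input_error")
  set.seed(52)
  for (k in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
})

de_fixture <- function(n = 30, fc = 1, sigma = 0.3, seed = 1) {
  design <- make_design(conditions = c("unstim", "PMA_Iono"))
  peptide_map <- data.frame(peptide = replicate(n, random_peptide()),
                            protein_id = sprintf("M%03d", 1:n),
                            stringsAsFactors = FALSE)
  effects <- data.frame(protein_id = peptide_map$protein_id,
                        condition = "PMA_Iono", fc = fc)
  tab <- simulate_intensities(design, peptide_map, effects,
                              sigma_log2 = sigma, seed = seed)
  assign <- mk_assign(tab$peptide, tab$protein_id)
  classes <- setNames(rep("microprotein", n), peptide_map$protein_id)
  q <- aggregate_proteins(tab, assign, classes, design$sample_id)
  list(q = q, design = design)
}

test_that("differential_expression computes t tests, BH and donor FCs", {
  fx <- de_fixture(n = 20, fc = 1, seed = 53)
  res <- differential_expression(fx$q, fx$design,
                                 c("PMA_Iono", "unstim"))
  expect_equal(nrow(res), 20)
  expect_true(all(res$adj_p >= res$p, na.rm = TRUE))
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
  # adjusted values are non-decreasing in the sorted p order
  o <- order(res$p)
  expect_true(!is.unsorted(res$adj_p[o]))
  # per-protein values match direct recomputation
  i <- 5
  sa <- fx$design$sample_id[fx$design$condition == "PMA_Iono"]
  sb <- fx$design$sample_id[fx$design$condition == "unstim"]
  a <- log2(unlist(fx$q[i, sa])); b <- log2(unlist(fx$q[i, sb]))
  expect_equal(res$p[i], t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(res$log2fc[i], log2(mean(2^a) / mean(2^b)))
  d1 <- fx$design$sample_id[fx$design$donor == "D1"]
  expect_equal(res$fc_donor_D1[i],
               mean(unlist(fx$q[i, intersect(sa, d1)])) /
                 mean(unlist(fx$q[i, intersect(sb, d1)])))
})

test_that("degenerate groups get the convention p values", {
  q <- data.frame(protein_id = "X", protein_class = "microprotein",
                  n_unique_peptides = 1L,
                  a1 = 4, a2 = 4, a3 = 4, b1 = 4, b2 = 4, b3 = 4,
                  stringsAsFactors = FALSE)
  design <- data.frame(
    sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    donor = rep(c("D1", "D2", "D3"), 2),
    condition = rep(c("act", "unstim"), each = 3),
    stringsAsFactors = FALSE
  )
  res <- differential_expression(q, design, c("act", "unstim"))
  expect_equal(res$log2fc, 0)
  expect_equal(res$p, 1)
})

test_that("planted effects are recovered on average", {
  est <- vapply(1:50, function(s) {
    fx <- de_fixture(n = 4, fc = 3, sigma = 0.3, seed = 1000 + s)
    res <- differential_expression(fx$q, fx$design,
                                   c("PMA_Iono", "unstim"))
    mean(res$log2fc)
  }, numeric(1))
  expect_lt(abs(mean(est) - log2(3)), 0.2)
})

test_that("call_deps applies strict thresholds", {
  res <- data.frame(
    protein_id = c("up", "edge_fc", "edge_p", "down", "null"),
    log2fc = log2(c(2.5, 2.0, 3.0, 0.4, 1.0)),
    p = rep(0.001, 5),
    adj_p = c(0.01, 0.01, 0.05, 0.01, 0.9),
    stringsAsFactors = FALSE
  )
  d <- call_deps(res)
  expect_equal(d$up, "up")
  expect_equal(d$down, "down")
  expect_false("edge_fc" %in% d$up)   # FC exactly 2.0
  expect_false("edge_p" %in% d$up)    # adj_p exactly 0.05
  expect_length(intersect(d$up, d$down), 0)
})

test_that("label_nascent follows the OPP / CHX ratio rule", {
  expect_equal(label_nascent(c(100, 120), numeric(0)), "nascent")
  expect_equal(label_nascent(c(100, 100), c(90, 90)), "pre_existing")
  expect_equal(label_nascent(c(100, 100), c(40, 40)), "nascent")
  expect_equal(label_nascent(numeric(0), numeric(0),
                             detected_global = TRUE), "pre_existing")
  expect_error(label_nascent(numeric(0), numeric(0),
                             detected_global = FALSE),
               class = "sorfpipe_input_error")
})

test_that("select_candidates enforces both criteria with strict bounds", {
  mk_res <- function(fcs) {
    data.frame(protein_id = "T1", protein_class = "microprotein",
               log2fc = 1, p = 0.01, adj_p = 0.02,
               fc_donor_D1 = fcs[1], fc_donor_D2 = fcs[2],
               fc_donor_D3 = fcs[3], stringsAsFactors = FALSE)
  }
  # passes: similarity 0.80, two donors above 1.50 in one contrast
  r <- select_candidates(list(PMA = mk_res(c(1.6, 1.7, 1.2)),
                              CD3 = mk_res(c(1.0, 1.0, 1.0))),
                         c(T1 = 0.80))
  expect_true(r$passes)
  expect_equal(r$n_supporting_donors, 2)
  # fails: one supporting donor in both contrasts
  r2 <- select_candidates(list(PMA = mk_res(c(1.6, 1.2, 1.1)),
                               CD3 = mk_res(c(1.6, 1.2, 1.1))),
                          c(T1 = 0.80))
  expect_false(r2$passes)
  expect_match(r2$reasons, "donor")
  # fails: similarity exactly at the 0.75 boundary
  r3 <- select_candidates(list(PMA = mk_res(c(2, 2, 2))), c(T1 = 0.75))
  expect_false(r3$passes)
  expect_match(r3$reasons, "similarity")
  # fold change exactly 1.50 does not count as supporting
  r4 <- select_candidates(list(PMA = mk_res(c(1.5, 1.5, 1.6))),
                          c(T1 = 0.9))
  expect_equal(r4$n_supporting_donors, 1)
  expect_false(r4$passes)
  # missing similarity is a failure reason, not an error
  r5 <- select_candidates(list(PMA = mk_res(c(2, 2, 2))), numeric(0))
  expect_false(r5$passes)
})
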