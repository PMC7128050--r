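test_that("risk scores are exact linear combinations", {
  expr <- matrix(c(2, 2), nrow = 2, dimnames = list(c("f1", "f2"), "p1"))
  expect_equal(unname(risk_score(c(f1 = 1, f2 = -1), expr)), 0)
  expect_equal(unname(risk_score(c(f1 = 2), rbind(f1 = 3))), 6)

  set.seed(2)
  expr2 <- matrix(rnorm(50), nrow = 5,
                  dimnames = list(paste0("f", 1:5), paste0("p", 1:10)))
  betas <- setNames(rnorm(5), paste0("f", 1:5))
  loop <- vapply(seq_len(10), function(j) {
    s <- 0
    for (f in names(betas)) s <- s + betas[[f]] * expr2[f, j]
    s
  }, 0)
  expect_equal(unname(risk_score(betas, expr2)), loop, tolerance = 1e-12)

  # linearity in the expression scale
  expect_equal(risk_score(betas, 3 * expr2), 3 * risk_score(betas, expr2))
  expect_error(risk_score(c(f9 = 1), expr2), "missing")
})

test_that("log-rank statistic matches the hand O-E/V formula on a printed toy", {
  # 6 patients, all events, groups interleaved
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1L, 6)
  grp <- c("A", "B", "A", "B", "A", "B")
  got <- logrank_test(grp, time, event)
  # hand formula: at each event time, O - E for group A and the
  # hypergeometric variance of the at-risk table
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n_a <- sum(at_risk & grp == "A")
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp == "A")
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  expect_equal(got$chisq, o_minus_e^2 / v, tolerance = 1e-10)
  expect_equal(got$p, pchisq(o_minus_e^2 / v, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("median dichotomization balances groups and catches tie collapse", {
  set.seed(5)
  scores <- rnorm(41)
  time <- rexp(41); event <- rbinom(41, 1, 0.8)
  out <- dichotomize_and_logrank(scores, time, event)
  expect_lte(abs(sum(out$group_labels == "high") - sum(out$group_labels == "low")), 1)
  # ties at the median go low
  expect_equal(sum(scores > median(scores)),
               sum(out$group_labels == "high"))
  expect_error(dichotomize_and_logrank(rep(1, 10), rexp(10), rep(1, 10)),
               class = "ncmod_tie_split")
})

test_that("extreme separation yields a vanishing log-rank p", {
  # all events early in the high group, none in the low group
  scores <- c(rep(2, 20), rep(-2, 20))
  time <- c(rexp(20, 1), rep(50, 20))
  event <- c(rep(1L, 20), rep(0L, 20))
  out <- dichotomize_and_logrank(scores, time, event)
  expect_lt(out$logrank_p, 1e-4)
})

test_that("univariate Cox beta solves the hand-written score equation", {
  # small instance: oracle is the root of the Breslow/Efron partial
  # likelihood score, written out by hand (no ties, so they coincide)
  x <- c(0.5, -1.2, 2.0, 0.3, -0.7)
  time <- c(2, 5, 1, 8, 4)
  event <- c(1L, 0L, 1L, 0L, 1L)
  score <- function(b) {
    s <- 0
    for (i in which(event == 1L)) {
      at_risk <- which(time >= time[i])
      w <- exp(b * x[at_risk])
      s <- s + x[i] - sum(x[at_risk] * w) / sum(w)
    }
    s
  }
  oracle <- uniroot(score, c(-5, 5), tol = 1e-10)$root
  expect_equal(cox_beta_per_factor(x, time, event), oracle, tolerance = 1e-6)

  expect_message(na1 <- cox_beta_per_factor(rep(1, 5), time, event), "constant")
  expect_true(is.na(na1))
  expect_message(na2 <- cox_beta_per_factor(x, time, c(1L, 0L, 0L, 0L, 0L)),
                 "fewer than 2 events")
  expect_true(is.na(na2))
})

test_that("a survival-neutral factor has a near-zero coefficient", {
  set.seed(8)
  betas <- replicate(30, {
    x <- matrix(rnorm(300), 1, dimnames = list("f", sprintf("p%03d", 1:300)))
    sv <- generate_survival(NULL, x, censoring_rate = 0.2,
                            seed = sample.int(1e6, 1), betas = c(f = 0))
    cox_beta_per_factor(x["f", ], sv$os_time, sv$os_event)
  })
  expect_lt(abs(mean(betas)), 0.1)
})

test_that("the with/without-ncRNA comparison runs both chains coherently", {
  set.seed(12)
  n <- 120
  gene <- matrix(rnorm(4 * n), 4,
                 dimnames = list(paste0("g", 1:4), sprintf("p%03d", 1:n)))
  nc <- matrix(rnorm(n), 1, dimnames = list("lncX", colnames(gene)))
  sv <- generate_survival(NULL, rbind(gene, nc), censoring_rate = 0.2, seed = 3,
                          betas = c(lncX = 1.2))
  cmp <- survival_comparison(gene, nc, sv$os_time, sv$os_event)
  expect_s3_class(cmp$genes_only, "ncmod_risk_model")
  expect_identical(cmp$improved,
                   cmp$genes_plus_ncrna$predictive_ability >
                     cmp$genes_only$predictive_ability)
  expect_true("lncX" %in% cmp$genes_plus_ncrna$factor_ids)
  expect_false("lncX" %in% cmp$genes_only$factor_ids)
  # risk scores reproduce sum(beta * expression) exactly
  rm <- cmp$genes_plus_ncrna
  expect_equal(rm$risk_scores,
               risk_score(rm$betas, rbind(gene, nc)), tolerance = 1e-12)
})
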