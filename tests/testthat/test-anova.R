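# aov-based oracle: sums of squares per stratum for the 2x3 mixed design
aov_oracle <- function(tab) {
  tab2 <- tab
  tab2$subject <- factor(tab2$subject)
  tab2$group <- factor(tab2$group)
  tab2$stimulus_type <- factor(tab2$stimulus_type)
  tab2$condition <- factor(tab2$condition)
  fit <- stats::aov(value ~ group * stimulus_type * condition +
                      Error(subject / (stimulus_type * condition)),
                    data = tab2)
  out <- list()
  for (stratum in summary(fit)) {
    s <- stratum[[1]]
    ss <- s[["Sum Sq"]]
    names(ss) <- trimws(rownames(s))
    out <- c(out, as.list(ss))
  }
  out
}

test_that("published sample sizes give the published degrees of freedom", {
  # groups of 19 and 23 subjects, 3-level within factor -> df (2, 80)
  tab <- random_mixed_table(n1 = 19, n2 = 23, seed = 1)
  an3 <- mixed_anova(collapse_within(tab, "condition"), within = "condition")
  i <- match("condition", an3$effect)
  expect_equal(an3$df[i], 2)
  expect_equal(an3$df_error[i], 80)
  # 2-level within factor -> df (1, 40); group df (1, 40)
  an2 <- mixed_anova(collapse_within(tab, "stimulus_type"),
                     within = "stimulus_type")
  j <- match("stimulus_type", an2$effect)
  expect_equal(an2$df[j], 1)
  expect_equal(an2$df_error[j], 40)
  k <- match("group", an2$effect)
  expect_equal(an2$df[k], 1)
  expect_equal(an2$df_error[k], 40)
})

test_that("sums of squares match the aov oracle on a random design", {
  tab <- random_mixed_table(n1 = 6, n2 = 5, seed = 7)
  an <- mixed_anova(tab, within = c("stimulus_type", "condition"))
  oracle <- aov_oracle(tab)
  pick <- function(effect) an$ss[match(effect, an$effect)]
  rel <- function(a, b) abs(a - b) / max(abs(b), 1e-12)
  expect_lt(rel(pick("group"), oracle$group), 1e-8)
  expect_lt(rel(pick("stimulus_type"), oracle$stimulus_type), 1e-8)
  expect_lt(rel(pick("condition"), oracle$condition), 1e-8)
  expect_lt(rel(pick("stimulus_type:group"),
                oracle[["group:stimulus_type"]]), 1e-8)
  expect_lt(rel(pick("condition:group"), oracle[["group:condition"]]), 1e-8)
  expect_lt(rel(pick("stimulus_type:condition"),
                oracle[["stimulus_type:condition"]]), 1e-8)
  expect_lt(rel(pick("stimulus_type:condition:group"),
                oracle[["group:stimulus_type:condition"]]), 1e-8)
  # error strata
  ss_err <- function(effect) an$ss_error[match(effect, an$effect)]
  expect_lt(rel(ss_err("group"), oracle$Residuals), 1e-8)
})

test_that("the sums of squares decompose the total exactly", {
  tab <- random_mixed_table(n1 = 5, n2 = 4, seed = 9)
  an <- mixed_anova(tab, within = c("stimulus_type", "condition"))
  # unique error strata: subject error + one per within effect
  err_between <- an$ss_error[match("group", an$effect)]
  within_effects <- c("stimulus_type", "condition",
                      "stimulus_type:condition")
  err_within <- sum(an$ss_error[match(within_effects, an$effect)])
  total_effects <- sum(an$ss)
  expect_equal(total_effects + err_between + err_within,
               attr(an, "ss_total"), tolerance = 1e-8)
})

test_that("partial eta squared follows its definition and stays in [0,1]", {
  tab <- random_mixed_table(seed = 13)
  an <- mixed_anova(tab, within = c("stimulus_type", "condition"))
  expect_equal(an$pes, an$ss / (an$ss + an$ss_error), tolerance = 1e-12)
  expect_true(all(an$pes >= 0 & an$pes <= 1))
  expect_true(all(an$df == round(an$df)))
})

test_that("a 2-level within effect reproduces the squared paired t", {
  set.seed(15)
  n <- 12
  tab <- data.frame(subject = rep(sprintf("s%02d", 1:n), 2),
                    condition = rep(c("a", "b"), each = n),
                    value = rnorm(2 * n))
  an <- mixed_anova(tab, within = "condition", between = NULL)
  tt <- paired_t(tab$value[tab$condition == "a"],
                 tab$value[tab$condition == "b"])
  i <- match("condition", an$effect)
  expect_equal(an$F[i], tt$t^2, tolerance = 1e-10)
  expect_equal(an$p[i], tt$p, tolerance = 1e-10)
  expect_equal(an$df_error[i], tt$df)
})

test_that("GG-corrected p is never below the uncorrected p", {
  tab <- random_mixed_table(n1 = 8, n2 = 7, seed = 17)
  an <- mixed_anova(tab, within = c("stimulus_type", "condition"))
  has_gg <- !is.na(an$p_gg)
  expect_true(any(has_gg))
  expect_true(all(an$p_gg[has_gg] >= an$p[has_gg]))
  expect_true(all(an$epsilon_gg[has_gg] <= 1 + 1e-12))
})

test_that("epsilon and Mauchly match the contrast-covariance formulas", {
  tab <- random_mixed_table(n1 = 9, n2 = 8, seed = 19)
  # oracle from first principles: subject x condition means, Helmert scores
  agg <- stats::aggregate(value ~ subject + condition + group, data = tab,
                          FUN = mean)
  subj <- sort(unique(agg$subject))
  lev <- sort(unique(agg$condition))
  Y <- matrix(NA_real_, length(subj), 3,
              dimnames = list(subj, lev))
  Y[cbind(match(agg$subject, subj), match(agg$condition, lev))] <- agg$value
  U <- Y %*% helmert_orth(3)
  grp <- factor(agg$group[match(subj, agg$subject)])
  S <- matrix(0, 2, 2)
  for (g in levels(grp)) {
    Ug <- U[grp == g, , drop = FALSE]
    S <- S + crossprod(sweep(Ug, 2, colMeans(Ug)))
  }
  n_err <- nrow(U) - nlevels(grp)
  S <- S / n_err
  eps_oracle <- sum(diag(S))^2 / (2 * sum(S * S))
  W_oracle <- det(S) / (mean(eigen(S)$values))^2
  rho <- 1 - (2 * 4 + 2 + 2) / (6 * 2 * n_err)
  chi_oracle <- -n_err * rho * log(W_oracle)
  expect_equal(gg_epsilon(tab, "condition"), eps_oracle, tolerance = 1e-10)
  ms <- mauchly(tab, "condition")
  expect_equal(ms$W, W_oracle, tolerance = 1e-10)
  expect_equal(ms$chi_sq, chi_oracle, tolerance = 1e-10)
  expect_equal(ms$df, 2)
  expect_equal(ms$p, stats::pchisq(chi_oracle, 2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_true(ms$W > 0 && ms$W <= 1)
})

test_that("spherical data give epsilon 1 and Mauchly W 1", {
  # contrast scores with exactly isotropic sample covariance
  U0 <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  Y <- U0 %*% t(helmert_orth(3)) + 5
  tab <- data.frame(subject = rep(sprintf("s%d", 1:4), 3),
                    condition = rep(c("a", "b", "c"), each = 4),
                    value = as.vector(Y))
  expect_equal(gg_epsilon(tab, "condition", between = NULL), 1,
               tolerance = 1e-12)
  ms <- mauchly(tab, "condition", between = NULL)
  expect_equal(ms$W, 1, tolerance = 1e-12)
  expect_equal(ms$p, 1, tolerance = 1e-12)
})

test_that("rank-one contrast covariance hits the epsilon lower bound", {
  z <- c(1, 2, -0.5, 3, -1.5)
  v <- c(1, 0, -1)
  Y <- outer(z, v)
  tab <- data.frame(subject = rep(sprintf("s%d", 1:5), 3),
                    condition = rep(c("a", "b", "c"), each = 5),
                    value = as.vector(Y))
  expect_equal(gg_epsilon(tab, "condition", between = NULL), 0.5,
               tolerance = 1e-12)
})

test_that("sphericity machinery rejects factors with under 3 levels", {
  tab <- random_mixed_table(seed = 21)
  expect_error(mauchly(tab, "stimulus_type"), "k < 3")
  expect_error(gg_epsilon(tab, "stimulus_type"), "k < 3")
})

test_that("mixed_anova validates its input", {
  tab <- random_mixed_table(n1 = 4, n2 = 4, seed = 23)
  dup <- rbind(tab, tab[1, ])
  expect_error(mixed_anova(dup, within = c("stimulus_type", "condition")),
               "duplicate cell")
  expect_error(mixed_anova(tab[-1, ],
                           within = c("stimulus_type", "condition")),
               "not complete")
  bad <- tab
  bad$group[bad$subject == "a01"][1] <- "g2"
  expect_error(mixed_anova(bad, within = c("stimulus_type", "condition")),
               "duplicate cell|more than one group")
  expect_error(mixed_anova(tab, dv = "nope", within = "condition"),
               "missing columns")
  one <- tab[tab$subject %in% c("a01", "b01"), ]
  expect_error(mixed_anova(one, within = c("stimulus_type", "condition")),
               "at least two subjects")
})

test_that("a single group drops the between terms with a notice", {
  tab <- random_mixed_table(seed = 25)
  tab$group <- "only"
  expect_message(an <- mixed_anova(tab,
                                   within = c("stimulus_type", "condition")),
                 "one group")
  expect_false("group" %in% an$effect)
  expect_false(any(grepl(":group", an$effect)))
})
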