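# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package.

# Classical mixed-design sums-of-squares decomposition from cell means, for a
# balanced design with one between factor and one or two within factors
# (equal group sizes). Returns a data.frame comparable to mixed_anova().
anova_oracle <- function(data, dv, subject, between, within) {
  y <- data[[dv]]
  s <- factor(data[[subject]])
  g_of_s <- tapply(as.character(data[[between]]), s, function(x) x[1])
  gm <- mean(y)
  n_s <- nlevels(s)
  G <- factor(data[[between]])
  mean_by <- function(...) tapply(y, list(...), mean)

  if (length(within) == 1L) {
    A <- factor(data[[within]])
    a <- nlevels(A)
    yg <- mean_by(G); ys <- mean_by(s); yi <- mean_by(A)
    ygi <- mean_by(G, A); ysi <- mean_by(s, A)
    n_g <- as.numeric(table(factor(g_of_s, levels = levels(G))))
    ss_tot <- sum((y - gm)^2)
    ss_subj <- a * sum((ys - gm)^2)
    ss_g <- a * sum(n_g * (yg - gm)^2)
    ss_swg <- ss_subj - ss_g
    ss_a <- n_s * sum((yi - gm)^2)
    ss_ga <- sum(n_g * (sweep(sweep(ygi, 1, yg), 2, yi) + gm)^2)
    ss_aswg <- ss_tot - ss_subj - ss_a - ss_ga
    dfs <- c(g = nlevels(G) - 1, swg = n_s - nlevels(G), a = a - 1,
             ga = (nlevels(G) - 1) * (a - 1),
             aswg = (a - 1) * (n_s - nlevels(G)))
    ms <- c(ss_g, ss_swg, ss_a, ss_ga, ss_aswg) / dfs
    out <- data.frame(
      effect = c(between, within, paste0(between, ":", within)),
      df_num = as.numeric(dfs[c("g", "a", "ga")]),
      df_den = as.numeric(dfs[c("swg", "aswg", "aswg")]),
      statistic = c(ms[1] / ms[2], ms[3] / ms[5], ms[4] / ms[5]),
      stringsAsFactors = FALSE
    )
    out$p_value <- stats::pf(out$statistic, out$df_num, out$df_den,
                             lower.tail = FALSE)
    return(out)
  }

  A <- factor(data[[within[1]]])
  B <- factor(data[[within[2]]])
  a <- nlevels(A); b <- nlevels(B); m <- a * b
  n_g <- as.numeric(table(factor(g_of_s, levels = levels(G))))
  ys <- mean_by(s); yg <- mean_by(G); yi <- mean_by(A); yj <- mean_by(B)
  ygi <- mean_by(G, A); ygj <- mean_by(G, B); yij <- mean_by(A, B)
  ysi <- mean_by(s, A); ysj <- mean_by(s, B); ygij <- mean_by(G, A, B)

  ss_tot <- sum((y - gm)^2)
  ss_subj <- m * sum((ys - gm)^2)
  ss_g <- m * sum(n_g * (yg - gm)^2)
  ss_swg <- ss_subj - ss_g
  ss_a <- n_s * b * sum((yi - gm)^2)
  ss_b <- n_s * a * sum((yj - gm)^2)
  ss_ga <- b * sum(n_g * (sweep(sweep(ygi, 1, yg), 2, yi) + gm)^2)
  ss_gb <- a * sum(n_g * (sweep(sweep(ygj, 1, yg), 2, yj) + gm)^2)
  ss_ab <- n_s * sum((sweep(sweep(yij, 1, yi), 2, yj) + gm)^2)

  gi_of_s <- function(mat) mat[cbind(match(g_of_s, rownames(mat)),
                                     rep(seq_len(ncol(mat)), each = n_s))]
  ss_aswg <- b * sum((as.vector(ysi) - rep(as.vector(ys), a) -
                        gi_of_s(ygi) + as.numeric(yg[g_of_s]))^2)
  ss_bswg <- a * sum((as.vector(ysj) - rep(as.vector(ys), b) -
                        gi_of_s(ygj) + as.numeric(yg[g_of_s]))^2)

  ss_gab <- 0
  for (g in levels(G)) for (i in levels(A)) for (j in levels(B)) {
    dev <- ygij[g, i, j] - ygi[g, i] - ygj[g, j] - yij[i, j] +
      yg[g] + yi[i] + yj[j] - gm
    ss_gab <- ss_gab + n_g[match(g, levels(G))] * dev^2
  }
  ss_abswg <- ss_tot - ss_subj - ss_a - ss_ga - ss_aswg - ss_b - ss_gb -
    ss_bswg - ss_ab - ss_gab

  nG <- nlevels(G)
  dfs <- list(
    g = nG - 1, swg = n_s - nG,
    a = a - 1, ga = (nG - 1) * (a - 1), aswg = (a - 1) * (n_s - nG),
    b = b - 1, gb = (nG - 1) * (b - 1), bswg = (b - 1) * (n_s - nG),
    ab = (a - 1) * (b - 1), gab = (nG - 1) * (a - 1) * (b - 1),
    abswg = (a - 1) * (b - 1) * (n_s - nG)
  )
  msw <- function(ss, df) ss / df
  ms_swg <- msw(ss_swg, dfs$swg)
  ms_aswg <- msw(ss_aswg, dfs$aswg)
  ms_bswg <- msw(ss_bswg, dfs$bswg)
  ms_abswg <- msw(ss_abswg, dfs$abswg)
  eff <- function(name, ss, dfn, ms_err, dfd) {
    f <- (ss / dfn) / ms_err
    data.frame(effect = name, df_num = dfn, df_den = dfd, statistic = f,
               p_value = stats::pf(f, dfn, dfd, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  rbind(
    eff(between, ss_g, dfs$g, ms_swg, dfs$swg),
    eff(within[1], ss_a, dfs$a, ms_aswg, dfs$aswg),
    eff(paste0(between, ":", within[1]), ss_ga, dfs$ga, ms_aswg, dfs$aswg),
    eff(within[2], ss_b, dfs$b, ms_bswg, dfs$bswg),
    eff(paste0(between, ":", within[2]), ss_gb, dfs$gb, ms_bswg, dfs$bswg),
    eff(paste0(within[1], ":", within[2]), ss_ab, dfs$ab, ms_abswg,
        dfs$abswg),
    eff(paste0(between, ":", within[1], ":", within[2]), ss_gab, dfs$gab,
        ms_abswg, dfs$abswg)
  )
}

# One-way between-subjects ANOVA from first principles.
oneway_oracle <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- table(groups)
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((values - means[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ss_b / df1) / (ss_w / df2)
  list(statistic = f, df_num = df1, df_den = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Pooled-variance two-sample t from the closed form.
t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, df = na + nb - 2L,
       p_value = 2 * stats::pt(-abs(t), na + nb - 2))
}

# Pearson correlation as a covariance ratio, p via the t transform.
r_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(estimate = r, statistic = t,
       p_value = 2 * stats::pt(-abs(t), n - 2))
}

# Step-by-step replay of the asymmetric delta rule over a trial log. Resets
# per session are supplied explicitly as a list of c(left, right) or NULL.
q_replay_oracle <- function(trials, params, resets) {
  qL <- NA_real_; qR <- NA_real_
  out <- matrix(NA_real_, nrow(trials), 2)
  for (k in seq_len(nrow(trials))) {
    row <- trials[k, ]
    if (row$trial_index == 0) {
      rs <- resets[[row$session_index + 1L]]
      if (!is.null(rs)) { qL <- rs[1]; qR <- rs[2] }
    }
    if (row$trial_type != "pavlovian_cue" && row$reward_boluses > 0) {
      if (row$choice == "left") {
        d <- row$reward_boluses - qL
        qL <- qL + (if (d >= 0) params$alpha_plus else params$alpha_minus) * d
      } else {
        d <- row$reward_boluses - qR
        qR <- qR + (if (d >= 0) params$alpha_plus else params$alpha_minus) * d
      }
    }
    out[k, ] <- c(qL, qR)
  }
  out
}

# Swap every left/right label in a trial log + session manifest.
mirror_log <- function(trials, sessions) {
  flip <- function(x) {
    out <- x
    out[x == "left"] <- "right"
    out[x == "right"] <- "left"
    out[x == "forced_left"] <- "forced_right"
    out[x == "forced_right"] <- "forced_left"
    out
  }
  trials$trial_type <- flip(trials$trial_type)
  trials$cue_side <- flip(trials$cue_side)
  trials$choice <- flip(trials$choice)
  sessions$shifted_side <- flip(sessions$shifted_side)
  sessions$risky_side <- flip(sessions$risky_side)
  list(trials = trials, sessions = sessions)
}

# Bare-bones subject plan for driving simulate_subject() directly.
mini_plan <- function(sessions, id = "S1", group = "WT_like",
                      anchor = "left") {
  list(subject_id = id, group = group,
       risk_condition_order = c("risky_better", "even", "safe_better"),
       initial_risky_side = "left", fallback_anchor_side = anchor,
       sessions = sessions)
}

tmpl <- function(...) riskshift:::session_template(...)

constant_boluses_of <- function(schedule, side) {
  riskshift:::constant_boluses(schedule, side)
}

# A reduced cohort configuration for fast simulation-based tests.
small_cohort_config <- function(n_clh = 4L, n_wt = 4L, seed = 11L,
                                phases = list(pavlovian = FALSE,
                                              baseline = FALSE)) {
  default_cohort_config(
    n_clh = n_clh, n_wt = n_wt, seed = seed,
    protocol = default_protocol_config(phases = phases)
  )
}

# A small balanced mixed-design table with integer responses: 2 groups x
# 2 subjects/group x 2 within factors (2 x 4 levels).
make_mixed_table <- function(n_per_group = 2, seed = 42, a_levels = 2,
                             b_levels = 4, integer_y = TRUE) {
  set.seed(seed)
  subj <- paste0("s", seq_len(2 * n_per_group))
  grp <- rep(c("g1", "g2"), each = n_per_group)
  d <- expand.grid(subject = subj, a = paste0("a", seq_len(a_levels)),
                   b = paste0("b", seq_len(b_levels)),
                   stringsAsFactors = FALSE)
  d$group <- grp[match(d$subject, subj)]
  d$y <- if (integer_y) sample(0:9, nrow(d), replace = TRUE)
         else rnorm(nrow(d))
  d
}

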