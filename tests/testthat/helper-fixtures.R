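# Shared fixtures and independent oracles for the test suite.

# Minimal 4-row global-measure table: 1 subject, 1 centre, 2 visits,
# 2 hemispheres.
toy_table <- function() {
  tibble::tibble(
    subject = "S01", centre = "A",
    visit = rep(1:2, each = 2),
    hemisphere = rep(c("left", "right"), 2),
    measure = "gm_volume",
    value = c(250, 255, 252, 249)
  )
}

write_toy_csv <- function(df = toy_table(), path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, na = "")
  path
}

# Balanced crossed table built from explicit effect draws (no call into
# the package generator), for oracle comparisons.
crossed_table <- function(n_s, n_c, n_v, n_h, mu = 100,
                          sd = c(subject = 0, centre = 0, visit = 0,
                                 sc = 0, sv = 0, cv = 0, scv = 0, e = 1),
                          seed = 42) {
  set.seed(seed)
  s <- sprintf("S%02d", 1:n_s); cn <- LETTERS[1:n_c]; vs <- 1:n_v
  h <- c("left", "right")[1:n_h]
  A <- rnorm(n_s, 0, sd["subject"]); B <- rnorm(n_c, 0, sd["centre"])
  C <- rnorm(n_v, 0, sd["visit"])
  AB <- matrix(rnorm(n_s * n_c, 0, sd["sc"]), n_s, n_c)
  AC <- matrix(rnorm(n_s * n_v, 0, sd["sv"]), n_s, n_v)
  BC <- matrix(rnorm(n_c * n_v, 0, sd["cv"]), n_c, n_v)
  ABC <- array(rnorm(n_s * n_c * n_v, 0, sd["scv"]), c(n_s, n_c, n_v))
  g <- expand.grid(hemisphere = h, visit = vs, centre = cn, subject = s,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(g$subject, s); j <- match(g$centre, cn); k <- match(g$visit, vs)
  g$value <- mu + A[i] + B[j] + C[k] + AB[cbind(i, j)] + AC[cbind(i, k)] +
    BC[cbind(j, k)] + ABC[cbind(i, j, k)] + rnorm(nrow(g), 0, sd["e"])
  g$measure <- "gm_volume"
  tibble::as_tibble(g)
}

# Independent OLS oracle: explicit normal equations.
ols_normal_equations <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# Independent EMS oracle for the a x b x c design with n replicates:
# sums of squares from base aov(), EMS coefficient matrix written out
# from the textbook expected-mean-squares rules, solved directly.
ems_oracle <- function(tbl) {
  df <- data.frame(
    s = factor(tbl$subject), c = factor(tbl$centre), v = factor(tbl$visit),
    y = tbl$value
  )
  a <- nlevels(df$s); b <- nlevels(df$c); cc <- nlevels(df$v)
  n <- nrow(df) / (a * b * cc)
  fit <- stats::aov(y ~ s * c * v, data = df)
  sm <- summary(fit)[[1]]
  ms_of <- function(nm) sm[trimws(rownames(sm)) == nm, "Mean Sq"]
  if (n > 1) {
    terms <- c("s", "c", "v", "s:c", "s:v", "c:v", "s:c:v")
    ms <- c(vapply(terms, ms_of, 1), ms_of("Residuals"))
    # rows: E(MS) of each term; cols: sigma2 of s,c,v,sc,sv,cv,scv,e
    M <- rbind(
      c(n * b * cc, 0, 0, n * cc, n * b, 0, n, 1),
      c(0, n * a * cc, 0, n * cc, 0, n * a, n, 1),
      c(0, 0, n * a * b, 0, n * b, n * a, n, 1),
      c(0, 0, 0, n * cc, 0, 0, n, 1),
      c(0, 0, 0, 0, n * b, 0, n, 1),
      c(0, 0, 0, 0, 0, n * a, n, 1),
      c(0, 0, 0, 0, 0, 0, n, 1),
      c(0, 0, 0, 0, 0, 0, 0, 1)
    )
    est <- solve(M, ms)
    names(est) <- c("subject", "centre", "visit", "subject:centre",
                    "subject:visit", "centre:visit", "subject:centre:visit",
                    "residual")
  } else {
    terms <- c("s", "c", "v", "s:c", "s:v", "c:v")
    ms <- c(vapply(terms, ms_of, 1), ms_of("s:c:v"))
    M <- rbind(
      c(b * cc, 0, 0, cc, b, 0, 1),
      c(0, a * cc, 0, cc, 0, a, 1),
      c(0, 0, a * b, 0, b, a, 1),
      c(0, 0, 0, cc, 0, 0, 1),
      c(0, 0, 0, 0, b, 0, 1),
      c(0, 0, 0, 0, 0, a, 1),
      c(0, 0, 0, 0, 0, 0, 1)
    )
    est <- solve(M, ms)
    names(est) <- c("subject", "centre", "visit", "subject:centre",
                    "subject:visit", "centre:visit", "residual")
  }
  est
}

# REML oracle via lme4 on the fully crossed random model.
reml_oracle <- function(tbl, include_threeway = TRUE) {
  df <- data.frame(
    s = factor(tbl$subject), c = factor(tbl$centre), v = factor(tbl$visit),
    y = tbl$value
  )
  fml <- if (include_threeway) {
    y ~ 1 + (1 | s) + (1 | c) + (1 | v) + (1 | s:c) + (1 | s:v) + (1 | c:v) +
      (1 | s:c:v)
  } else {
    y ~ 1 + (1 | s) + (1 | c) + (1 | v) + (1 | s:c) + (1 | s:v) + (1 | c:v)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = df,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- setNames(vc$vcov, vc$grp)
  map <- c(
    s = "subject", c = "centre", v = "visit",
    `s:c` = "subject:centre", `s:v` = "subject:visit", `c:v` = "centre:visit",
    `s:c:v` = "subject:centre:visit", Residual = "residual"
  )
  names(out) <- map[names(out)]
  out
}
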