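# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately implemented without the package's own code
# paths (and without glmnet), so agreement is evidence, not tautology.

# FISTA (accelerated proximal gradient) minimizer of
# (1/(2n)) * ||y - w0 - X w||^2 + lam * ||w||_1, intercept unpenalized.
fista_lasso <- function(X, y, lam, iters = 20000) {
  n <- nrow(X)
  Xc <- cbind(1, X)
  L <- max(eigen(crossprod(Xc) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  w <- rep(0, ncol(Xc)); z <- w; tk <- 1
  for (i in seq_len(iters)) {
    g <- crossprod(Xc, Xc %*% z - y) / n
    wn <- as.numeric(z - g / L)
    wn[-1] <- sign(wn[-1]) * pmax(abs(wn[-1]) - lam / L, 0)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- wn + ((tk - 1) / tn) * (wn - w)
    w <- wn; tk <- tn
  }
  w  # c(intercept, weights)
}

lasso_objective <- function(X, y, lam, w0, w) {
  r <- y - w0 - as.numeric(X %*% w)
  sum(r^2) / (2 * length(y)) + lam * sum(abs(w))
}

# brute-force BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# brute-force AUROC by pairwise comparison, ties = 0.5
auroc_bruteforce <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# small labelled dataset built in code: TFs t1..t3 plus targets g1..g2
tiny_dataset <- function(seed = 42, n_control = 10, n_case = 8) {
  set.seed(seed)
  n <- n_control + n_case
  tf <- matrix(rnorm(3 * n), nrow = 3,
               dimnames = list(c("t1", "t2", "t3"),
                               sprintf("s%02d", seq_len(n))))
  g1 <- 1 + 2 * tf["t1", ] - tf["t3", ] + rnorm(n, sd = 0.1)
  g2 <- -0.5 + 0.8 * tf["t2", ] + rnorm(n, sd = 0.1)
  vals <- rbind(tf, g1 = g1, g2 = g2)
  syms <- c(t1 = "TFA", t2 = "TFB", t3 = "TFC", g1 = "GENE1", g2 = "GENE2")
  expression_dataset(vals, rep(c("control", "case"), c(n_control, n_case)),
                     dataset_id = "tiny", feature_symbols = syms)
}

# minimal RegulatoryModel for cascade/transfer fixtures
make_model <- function(target, weights = numeric(0), intercept = 0) {
  structure(
    list(target_id = target, intercept = intercept,
         weights = weights, penalty = 1, n_train = 10,
         train_dataset_id = "fixture", converged = TRUE),
    class = "RegulatoryModel"
  )
}

# write a small series-matrix fixture; `rows` defaults to a well-formed table
write_sm_fixture <- function(path,
                             header = c("ID_REF", "GSM1", "GSM2"),
                             rows = list(c("f1", "1.5", "2.5"),
                                         c("f2", "0.25", "-1"),
                                         c("f3", "3", "4")),
                             characteristics = c("tissue: tumor",
                                                 "tissue: normal"),
                             delimiters = TRUE) {
  q <- function(x) paste0('"', x, '"')
  lines <- c(
    paste0("!Series_geo_accession\t", q("GSEFIX")),
    paste("!Sample_geo_accession", paste(q(header[-1]), collapse = "\t"),
          sep = "\t"),
    paste("!Sample_characteristics_ch1", paste(q(characteristics),
                                               collapse = "\t"), sep = "\t")
  )
  if (delimiters) lines <- c(lines, "!series_matrix_table_begin")
  lines <- c(lines, paste(q(header), collapse = "\t"))
  for (r in rows) {
    lines <- c(lines, paste(c(q(r[1]), r[-1]), collapse = "\t"))
  }
  if (delimiters) lines <- c(lines, "!series_matrix_table_end")
  writeLines(lines, path)
  path
}
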