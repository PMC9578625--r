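# Independent oracles and fixture builders shared across tests.
# The oracle code deliberately re-derives every statistic from scratch
# (explicit loops, no calls into the package's fitting path).

# log multivariate normal density, via Cholesky
log_mvn <- function(x, mu, S) {
  ch <- chol(S)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * (length(mu) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z * z))
}

# Brute-force shared-covariance Gaussian Bayes classifier.  Recomputes
# class means, the pooled covariance (1/N sum n_k S_k with population
# S_k) and priors directly from the raw data, then predicts
# argmax_k log pi_k + log N(x; mu_k, S_pooled).  Ties: alphabetical.
oracle_bayes_predict <- function(train_x, train_y, queries) {
  classes <- sort(unique(train_y))
  N <- nrow(train_x); M <- ncol(train_x)
  mus <- list(); S <- matrix(0, M, M)
  for (k in classes) {
    xk <- train_x[train_y == k, , drop = FALSE]
    mu <- colMeans(xk)
    mus[[k]] <- mu
    for (i in seq_len(nrow(xk))) {
      d <- xk[i, ] - mu
      S <- S + outer(d, d)          # sum over points = n_k * S_k summed
    }
  }
  S <- S / N
  apply(queries, 1L, function(x) {
    ll <- vapply(classes, function(k)
      log(sum(train_y == k) / N) + log_mvn(x, mus[[k]], S), numeric(1))
    classes[which.max(ll)]
  })
}

# a random small labeled instance: K classes, M features, n per class
random_instance <- function(K, M, n_per_class) {
  classes <- LETTERS[seq_len(K)]
  A <- matrix(rnorm(M * M), M)
  S <- crossprod(A) / M + diag(M)   # well-conditioned shared covariance
  ch <- chol(S)
  x <- NULL; y <- character(0)
  for (k in seq_len(K)) {
    mu <- rnorm(M, sd = 2)
    n <- n_per_class[min(k, length(n_per_class))]
    x <- rbind(x, matrix(rnorm(n * M), n) %*% ch +
                 matrix(mu, n, M, byrow = TRUE))
    y <- c(y, rep(classes[k], n))
  }
  colnames(x) <- canonical_shifts()[seq_len(M)]
  list(x = x, y = y, classes = classes)
}

# hand-built model with a fixed pooled covariance (for closed-form
# limit checks); mirrors the documented shiftlda_model fields
manual_model <- function(means, pooled_cov, priors) {
  classes <- rownames(means)
  structure(list(
    shift_names = colnames(means), subset = NULL, classes = classes,
    means = means, counts = stats::setNames(rep(2L, length(classes)), classes),
    priors = priors, pooled_cov = pooled_cov,
    pooled_cov_inv = solve(pooled_cov),
    per_class_cov = stats::setNames(
      rep(list(pooled_cov), length(classes)), classes),
    regularization_lambda = 0, scaling = NULL, N = 2L * length(classes)
  ), class = "shiftlda_model")
}

# a strongly separated class model over a few residue types: means
# placed far apart relative to the (shared diagonal) scatter
separated_class_model <- function(types = c("A", "G", "L", "S", "V"),
                                  sep = 10, sd = 1) {
  base <- default_class_model()
  keep <- match(types, base$classes)
  means <- base$means[keep, , drop = FALSE]
  for (j in seq_len(ncol(means)))
    means[, j] <- ifelse(is.na(means[, j]), NA,
                         sep * sd * seq_along(types))
  sds <- base$sds[keep, , drop = FALSE]
  sds[!is.na(sds)] <- sd
  class_model(types, means, sds,
              stats::setNames(rep(1 / length(types), length(types)), types))
}

# serialize a spin table as a minimal NMR-STAR 3 entry (text lines)
star3_entry <- function(spins, entry_id = "synthetic") {
  atom_rows <- character(0)
  n <- 0L
  for (i in seq_len(nrow(spins))) {
    res3 <- names(which(shiftlda:::AA3TO1 == spins$residue_type[i]))
    for (s in canonical_shifts()) {
      v <- spins[[s]][i]
      if (is.na(v)) next
      n <- n + 1L
      atom <- c(HN = "H", N = "N", CO = "C", CA = "CA", CB = "CB",
                HA = "HA", HB = "HB")[[s]]
      atom_rows <- c(atom_rows, sprintf(
        "     %d 1 %d %d %s %s . %.4f 0.05 1",
        n, spins$sequence_position[i], spins$sequence_position[i],
        res3, atom, v))
    }
  }
  c(paste0("data_", entry_id),
    "save_assigned_chemical_shifts",
    "   _Assigned_chem_shift_list.Sf_category assigned_chemical_shifts",
    "   loop_",
    "      _Atom_chem_shift.ID",
    "      _Atom_chem_shift.Entity_ID",
    "      _Atom_chem_shift.Comp_index_ID",
    "      _Atom_chem_shift.Seq_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Ambiguity_code",
    "      _Atom_chem_shift.Val",
    "      _Atom_chem_shift.Val_err",
    "      _Atom_chem_shift.Assign_fig_of_merit",
    atom_rows,
    "   stop_",
    "save_")
}
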