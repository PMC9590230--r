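# Fixtures are built in code: small record tibbles in the on-disk schema,
# written to temp files where a file is needed.

make_records <- function(rows) {
  defaults <- list(client_id = "c1", clinic_id = "clinic_1",
                   visit_date = as.Date("2018-03-01"), hcw_id = "h1",
                   cadre = "NURSE", start = 540L, end = 560L,
                   nonprep_minutes = 0, activities = list("BLOOD_TESTING"),
                   months_since_prep_start = 5L)
  out <- lapply(rows, function(r) {
    # modifyList() would merge list-columns recursively; replace instead
    row <- defaults
    for (nm in names(r)) row[[nm]] <- r[[nm]]
    tibble::tibble(
      client_id = row$client_id, clinic_id = row$clinic_id,
      visit_date = as.Date(row$visit_date), hcw_id = row$hcw_id,
      cadre = row$cadre, start = as.integer(row$start),
      end = as.integer(row$end), nonprep_minutes = row$nonprep_minutes,
      activities = if (is.list(row$activities)) row$activities
                   else list(row$activities),
      months_since_prep_start = as.integer(row$months_since_prep_start)
    )
  })
  dplyr::bind_rows(out)
}

write_record_file <- function(records, path = tempfile(fileext = ".csv")) {
  write_records(records, path)
  path
}

# Independent least-squares oracle: pseudoinverse via the normal equations,
# classical covariance, t-based CIs.  Deliberately avoids lm().
ols_oracle <- function(X, y, level = 0.95) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- drop(XtX_inv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  n <- nrow(X); k <- ncol(X)
  sigma2 <- sum(res^2) / (n - k)
  V <- sigma2 * XtX_inv
  se <- sqrt(diag(V))
  tq <- stats::qt(1 - (1 - level) / 2, n - k)
  list(beta = setNames(beta, colnames(X)), vcov = V,
       ci_low = beta - tq * se, ci_high = beta + tq * se,
       rss = sum(res^2), sigma2 = sigma2)
}

random_design <- function(n, k, seed) {
  set.seed(seed)
  X <- cbind(constant = 1,
             matrix(rnorm(n * (k - 1)), n, k - 1,
                    dimnames = list(NULL, paste0("x", seq_len(k - 1)))))
  y <- drop(X %*% runif(k, -2, 2)) + rnorm(n)
  list(X = X, y = y)
}
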