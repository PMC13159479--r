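# Independent brute-force oracles. Each is a deliberately naive, literal
# implementation kept separate from the package's code paths.

# buffer exposure: plain double loop over every (application, address-year)
oracle_buffer_exposure <- function(applications, addresses, radius_m = 500) {
  rows <- list()
  for (i in seq_len(nrow(addresses))) {
    a <- addresses[i, ]
    for (j in seq_len(nrow(applications))) {
      ap <- applications[j, ]
      if (ap$year < a$start_year || ap$year > a$end_year) next
      if (sqrt((ap$x - a$x)^2 + (ap$y - a$y)^2) > radius_m) next
      key <- paste(a$participant_id, ap$chemical_code, ap$year)
      rows[[key]] <- (if (is.null(rows[[key]])) 0 else rows[[key]]) +
        ap$pounds / ap$acres
    }
  }
  if (!length(rows))
    return(data.frame(participant_id = character(),
                      chemical_code = integer(), year = integer(),
                      exposure = numeric()))
  parts <- do.call(rbind, strsplit(names(rows), " "))
  out <- data.frame(participant_id = parts[, 1],
                    chemical_code = as.integer(parts[, 2]),
                    year = as.integer(parts[, 3]),
                    exposure = unlist(rows), stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$chemical_code, out$year), ]
  rownames(out) <- NULL
  out
}

# winsorization per row with the (k-1)/(n-1) interpolation convention
oracle_winsorize_row <- function(v, lq = 0.05, uq = 0.95) {
  qfun <- function(p) {
    n <- length(v)
    s <- sort(v)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  pmin(pmax(v, qfun(lq)), qfun(uq))
}

# OLS residuals via explicit normal equations
oracle_ols_residuals <- function(y, X) {
  beta <- solve(t(X) %*% X) %*% t(X) %*% y
  as.vector(y - X %*% beta)
}

# Benjamini-Hochberg step-up, literal
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# clustering by an all-pairs gap check: two probes share a cluster iff a
# chain of consecutive-by-position steps <= max_gap connects them
oracle_cluster <- function(annot, max_gap) {
  annot <- annot[order(annot$chromosome, annot$position), ]
  ids <- integer(nrow(annot))
  cl <- 0L
  for (i in seq_len(nrow(annot))) {
    if (i == 1L ||
        annot$chromosome[i] != annot$chromosome[i - 1L] ||
        annot$position[i] - annot$position[i - 1L] > max_gap) cl <- cl + 1L
    ids[i] <- cl
  }
  data.frame(probe_id = annot$probe_id, cluster = ids)
}

# run-length scan for exceedance regions
oracle_bumps <- function(smoothed, cluster, cutoff, min_probes) {
  res <- list()
  i <- 1L
  n <- length(smoothed)
  while (i <= n) {
    s <- if (smoothed[i] > cutoff) 1L else if (smoothed[i] < -cutoff) -1L
         else 0L
    if (s == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && cluster[j + 1L] == cluster[i] &&
           ((s == 1L && smoothed[j + 1L] > cutoff) ||
            (s == -1L && smoothed[j + 1L] < -cutoff))) j <- j + 1L
    if (j - i + 1L >= min_probes)
      res[[length(res) + 1L]] <- data.frame(
        idx_start = i, idx_end = j, n_probes = j - i + 1L,
        area = sum(abs(smoothed[i:j]) - cutoff), sign = s)
    i <- j + 1L
  }
  if (!length(res)) return(data.frame(idx_start = integer(),
                                      idx_end = integer(),
                                      n_probes = integer(),
                                      area = numeric(), sign = integer()))
  do.call(rbind, res)
}

# literal transcription of the published biweight midcorrelation formulas
oracle_bicor <- function(x, y, cc = 9) {
  med_x <- median(x); med_y <- median(y)
  mad_x <- median(abs(x - med_x)); mad_y <- median(abs(y - med_y))
  ux <- (x - med_x) / (cc * mad_x)
  uy <- (y - med_y) / (cc * mad_y)
  wx <- (1 - ux^2)^2 * (abs(ux) < 1)
  wy <- (1 - uy^2)^2 * (abs(uy) < 1)
  num <- sum(wx * (x - med_x) * wy * (y - med_y))
  num / (sqrt(sum((wx * (x - med_x))^2)) * sqrt(sum((wy * (y - med_y))^2)))
}

# step-by-step moderated-t: per-probe simple regression, then the
# log-variance moment equations solved with uniroot on trigamma
oracle_moderated <- function(R, x, df_resid = NULL) {
  n <- ncol(R)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  d <- if (is.null(df_resid)) n - 2 else df_resid
  slope <- s2 <- numeric(nrow(R))
  for (g in seq_len(nrow(R))) {
    y <- R[g, ] - mean(R[g, ])
    slope[g] <- sum(y * xc) / sxx
    s2[g] <- (sum(y^2) - slope[g]^2 * sxx) / d
  }
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  ev <- var(e) - trigamma(d / 2)
  if (ev > 0) {
    f <- function(v) trigamma(v) - ev
    half_d0 <- uniroot(f, c(1e-8, 1e8), tol = 1e-14)$root
    d0 <- 2 * half_d0
    s0 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  } else {
    d0 <- 1e7
    s0 <- exp(mean(e))
  }
  s2p <- (d0 * s0 + d * s2) / (d0 + d)
  tt <- slope / sqrt(s2p / sxx)
  list(df_prior = d0, var_prior = s0, t = tt,
       p = 2 * pt(-abs(tt), df = d + d0))
}

# Wallenius pmf by the single-integral representation (substituted form),
# usable on small universes only
oracle_wallenius_pmf <- function(x, m1, m2, n, w) {
  d <- w * (m1 - x) + (m2 - (n - x))
  I <- integrate(function(u) d * (1 - u^w)^x * (1 - u)^(n - x) * u^(d - 1),
                 0, 1, rel.tol = 1e-12, subdivisions = 2000L)$value
  choose(m1, x) * choose(m2, n - x) * I
}

oracle_wallenius_tail <- function(k, m1, m2, n, w) {
  sum(vapply(k:min(n, m1), oracle_wallenius_pmf, numeric(1),
             m1 = m1, m2 = m2, n = n, w = w))
}

# brute-force probe->gene grouping
oracle_map_genes <- function(selected, annot) {
  ann <- annot[nzchar(annot$gene) & !is.na(annot$gene), ]
  genes <- toupper(ann$gene)
  universe <- sort(unique(genes))
  cnt <- vapply(universe, function(g) sum(genes == g), integer(1))
  sel <- sort(unique(genes[ann$probe_id %in% selected]))
  list(selected = sel, universe = universe, cpgs_per_gene = cnt)
}

# positional Jaccard of two intervals
jaccard_interval <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1) + 1)
  inter / (max(a2, b2) - min(a1, b1) + 1)
}
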