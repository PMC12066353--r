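# Small deterministic fixtures and independent oracle implementations used
# across the suite. Oracles are deliberately written as plain brute force,
# independent of the package's computational paths.

fns4 <- c("scavenging", "myrmecochory", "granivory", "plant_protection")

named4 <- function(x) stats::setNames(rep_len(x, 4), fns4)

toy_design <- function(n_blocks = 1, plots_per_zone = 1, quarters = 1,
                       events = 1) {
  g <- expand.grid(quarter = paste0("q", seq_len(quarters)),
                   plot_i = seq_len(plots_per_zone),
                   zone = c("control", "suppression"),
                   block = paste0("B", seq_len(n_blocks)),
                   event = seq_len(events), stringsAsFactors = FALSE)
  g$zone_id <- paste(g$block, g$zone, sep = ":")
  g$plot <- paste0(g$block, "_", substr(g$zone, 1, 1), "p", g$plot_i)
  g$sample_id <- paste(g$plot, g$quarter, paste0("e", g$event), sep = ".")
  g[, c("sample_id", "block", "zone", "zone_id", "plot", "quarter", "event")]
}

toy_community <- function(abund, design = NULL, targets = character()) {
  if (is.null(design)) {
    design <- toy_design(n_blocks = ceiling(nrow(abund) / 2))
    design <- design[seq_len(nrow(abund)), ]
    rownames(abund) <- design$sample_id
  }
  community_matrix(abund, design, targets)
}

# --- independent oracles ----------------------------------------------------

# brute-force Gower: explicit double loop over species pairs and traits
oracle_gower <- function(df, types) {
  tcols <- names(types)
  n <- nrow(df)
  D <- matrix(0, n, n, dimnames = list(df$species, df$species))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (tr in tcols) {
      xi <- df[[tr]][i]; xj <- df[[tr]][j]
      if (is.na(xi) || is.na(xj)) next
      contrib <- if (types[[tr]] %in% c("continuous", "ordinal")) {
        rng <- diff(range(df[[tr]], na.rm = TRUE))
        if (rng == 0) next
        abs(as.numeric(xi) - as.numeric(xj)) / rng
      } else as.numeric(xi != xj)
      num <- num + contrib; den <- den + 1
    }
    D[i, j] <- num / den
  }
  D
}

# brute-force weighted classical scaling via explicit eigendecomposition
oracle_wpcoa <- function(D, w) {
  n <- nrow(D)
  w <- w / sum(w)
  A <- -0.5 * D^2
  ones <- rep(1, n)
  C <- diag(n) - ones %*% t(w)          # row-weighted centring projector
  B <- C %*% A %*% t(C)
  Ws <- diag(sqrt(w))
  E <- eigen(Ws %*% B %*% Ws, symmetric = TRUE)
  keep <- E$values > 1e-10
  U <- diag(1 / sqrt(w)) %*% E$vectors[, keep, drop = FALSE]
  coords <- U %*% diag(sqrt(E$values[keep]), sum(keep))
  list(coords = coords, eig = E$values)
}

# textbook Spearman: Pearson correlation of ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exhaustive null distribution of shared species between two null draws,
# enumerating ordered weighted draws without replacement by recursion
oracle_shared_dist <- function(k1, k2, w) {
  w <- w / sum(w)
  draws <- function(k) {
    # returns list of list(set, prob) over all ordered draws, aggregated
    acc <- new.env()
    recurse <- function(chosen, prob) {
      if (length(chosen) == k) {
        key <- paste(sort(chosen), collapse = ",")
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + prob
        return(invisible())
      }
      rem <- setdiff(seq_along(w), chosen)
      denom <- sum(w[rem])
      for (s in rem) recurse(c(chosen, s), prob * w[s] / denom)
    }
    recurse(integer(), 1)
    out <- lapply(ls(acc), function(key)
      list(set = as.integer(strsplit(key, ",")[[1]]), prob = acc[[key]]))
    out
  }
  d1 <- draws(k1); d2 <- draws(k2)
  dist <- numeric(min(k1, k2) + 1)
  for (a in d1) for (b in d2) {
    sh <- length(intersect(a$set, b$set))
    dist[sh + 1] <- dist[sh + 1] + a$prob * b$prob
  }
  dist
}

# gift-wrapping (Jarvis march) convex hull + triangle-fan area
oracle_hull_area <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  start <- which.min(xy[, 1] + 1e-12 * xy[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    nxt <- cand[1]
    for (q in cand[-1])
      if (cross(xy[p, ], xy[nxt, ], xy[q, ]) < 0) nxt <- q
    if (nxt == start) break
    hull <- c(hull, nxt)
    if (length(hull) > n) stop("hull construction failed")
  }
  if (length(hull) < 3) return(0)
  pts <- xy[hull, , drop = FALSE]
  a <- 0
  for (i in 2:(nrow(pts) - 1))
    a <- a + cross(pts[1, ], pts[i, ], pts[i + 1, ]) / 2
  unname(abs(a))
}
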