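# Shared fixtures and independent oracles used across the test files.
# Cohorts are cached per-session so repeated test files don't regenerate them.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# default-condition cohort with rendered volumes (small, for image tests)
test_cohort_rendered <- function() {
  cached("rendered", generate_cohort(generator_config(120L, seed = 101L)))
}

# biomarker-only cohort at moderate size
test_cohort_tabular <- function(n = 600L, seed = 102L, ...) {
  cached(paste0("tab", n, seed), generate_cohort(
    generator_config(n, render = FALSE, seed = seed, ...)))
}

# digitized sphere mask of radius r voxels in an n^3 grid
sphere_mask <- function(r, n = 2L * r + 6L) {
  g <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  array(d2 <= r^2, c(n, n, n))
}

# brute-force pairwise-concordance AUC: (#{pos>neg} + 0.5 #{pos=neg})/(n1 n0)
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# brute-force maximum pairwise distance per axial slice
brute_axial_diameter <- function(mask, spacing) {
  best <- 0
  for (z in seq_len(dim(mask)[3])) {
    ij <- which(mask[, , z], arr.ind = TRUE)
    if (nrow(ij) < 2) next
    for (a in seq_len(nrow(ij) - 1)) for (b in (a + 1):nrow(ij)) {
      d <- unname(sqrt(((ij[a, 1] - ij[b, 1]) * spacing[1])^2 +
                         ((ij[a, 2] - ij[b, 2]) * spacing[2])^2))
      if (d > best) best <- d
    }
  }
  best
}

# brute-force KNN by full distance sort (stable ties, odd k majority)
brute_knn <- function(train_x, train_y, query_x, k) {
  apply(query_x, 1, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    nn <- order(d)[seq_len(k)]
    as.integer(sum(train_y[nn]) * 2 > k)
  })
}

# even-odd point-in-polygon oracle with explicit boundary exclusion; pixel
# centers at integer coordinates, polygon vertices `poly` (n x 2), 0-based
pip_strict_oracle <- function(poly, nx, ny) {
  on_segment <- function(x, y, x1, y1, x2, y2) {
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    if (abs(cross) > 1e-9) return(FALSE)
    x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
      y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9
  }
  nv <- nrow(poly)
  nxt <- c(2:nv, 1)
  out <- matrix(FALSE, nx, ny)
  for (x in 0:(nx - 1)) for (y in 0:(ny - 1)) {
    on_b <- FALSE
    for (i in seq_len(nv)) {
      if (on_segment(x, y, poly[i, 1], poly[i, 2], poly[nxt[i], 1], poly[nxt[i], 2])) {
        on_b <- TRUE; break
      }
    }
    if (on_b) next
    crossings <- 0L
    for (i in seq_len(nv)) {
      y1 <- poly[i, 2]; y2 <- poly[nxt[i], 2]
      if (y1 == y2) next
      if (min(y1, y2) <= y && y < max(y1, y2)) {
        xc <- poly[i, 1] + (y - y1) / (y2 - y1) * (poly[nxt[i], 1] - poly[i, 1])
        if (xc > x) crossings <- crossings + 1L
      }
    }
    out[x + 1, y + 1] <- crossings %% 2L == 1L
  }
  out
}

# star-convex integer polygon around a center, for rasterization tests
random_star_polygon <- function(n_vertices, cx, cy, r_min, r_max) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_min, r_max)
  cbind(round(cx + r * cos(ang)), round(cy + r * sin(ang)))
}
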