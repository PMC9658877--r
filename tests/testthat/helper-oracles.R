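# Independent oracles kept deliberately naive: brute-force double loops,
# matrix-power reachability, dynamic programming. They never call the code
# paths they check.

# brute-force block percentages: double loop over all residue pairs
oracle_block_fractions <- function(values, chain_of, dom_of, threshold = 10,
                                   adjacency = "cyclic") {
  L <- nrow(values)
  n_chains <- max(chain_of)
  adj_ok <- function(a, b) {
    if (a == b) return(FALSE)
    if (adjacency == "all_pairs" || n_chains <= 2) return(TRUE)
    d <- abs(a - b)
    d == 1 || d == n_chains - 1
  }
  counts <- list()
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    di <- dom_of[i]; dj <- dom_of[j]
    if (is.na(di) || is.na(dj) || di == "hinge" || dj == "hinge") next
    v <- (values[i, j] + values[j, i]) / 2
    cls <- if (di == dj && chain_of[i] == chain_of[j]) {
      paste0("intra-", di)
    } else if (di == dj && adj_ok(chain_of[i], chain_of[j])) {
      paste0("inter-", di)
    } else if (di != dj) {
      "cross-domain"
    } else NA
    if (is.na(cls)) next
    if (is.null(counts[[cls]])) counts[[cls]] <- c(0L, 0L)
    counts[[cls]][1] <- counts[[cls]][1] + 1L
    if (v < threshold) counts[[cls]][2] <- counts[[cls]][2] + 1L
  }
  out <- data.frame(block = names(counts),
                    pair_count = vapply(counts, `[`, integer(1), 1),
                    fraction_below = vapply(counts, function(x)
                      100 * x[2] / x[1], numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$block), ]
}

# connected components by boolean matrix powers (reachability closure)
oracle_components <- function(adjacency_matrix, ids) {
  n <- nrow(adjacency_matrix)
  reach <- adjacency_matrix | diag(TRUE, n)
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  comp_key <- apply(reach, 1, function(r) paste(which(r), collapse = ","))
  comps <- split(ids, comp_key)
  names(comps) <- NULL
  comps[order(-lengths(comps), vapply(comps, `[`, character(1), 1))]
}

# Needleman-Wunsch with affine gaps (match 1 / mismatch 0; a gap of length g
# costs open + ext * g, the Biostrings convention); returns the optimal score
oracle_nw_score <- function(a, b, open = 10, ext = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- as.numeric(a[i - 1] == b[j - 1])
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# high-density numerical SASA oracle for small atom sets (plain loops)
oracle_sasa <- function(xyz, radii, probe = 1.4, npts = 100000L) {
  n <- nrow(xyz)
  ext <- radii + probe
  i_ <- seq_len(npts) - 0.5
  phi <- acos(1 - 2 * i_ / npts)
  theta <- pi * (1 + sqrt(5)) * i_
  sph <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  total <- 0
  for (i in seq_len(n)) {
    pts <- sweep(sph * ext[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, npts)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > ext[j]^2
    }
    total <- total + 4 * pi * ext[i]^2 * sum(acc) / npts
  }
  total
}

random_rotation <- function() {
  # QR of a Gaussian matrix, determinant forced positive
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# small helper: a fresh generated pentamer + domain map, reused across tests
fixture_pentamer <- function(seed = 7, n = 5, noise = 0, open = 0,
                             btb = 16L, hinge = 4L, ctd = 16L) {
  ch <- make_chain(synthetic_spec(btb = btb, hinge = hinge, ctd = ctd,
                                  seed = seed))
  model <- make_cn_assembly(ch$model, n, ring_radius = 14,
                            noise_sigma = noise, open_displacement = open,
                            seed = seed + 100)
  list(chain = ch, model = model)
}
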