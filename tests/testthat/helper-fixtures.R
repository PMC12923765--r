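# In-code fixtures and independent oracles shared across the suite.

# --- toy protein ------------------------------------------------------------

# residue templates: atom names + local coordinates (rough geometry; tests
# only rely on names, elements and relative positions)
res_template <- function(res_name) {
  base <- list(
    GLY = list(name = c("N", "CA", "C", "O"),
               xyz = rbind(c(0, 0, 0), c(1.4, 0.2, 0), c(2.2, 1.2, 0.6),
                           c(2.0, 2.4, 0.6))),
    ALA = list(name = c("N", "CA", "C", "O", "CB"),
               xyz = rbind(c(0, 0, 0), c(1.4, 0.2, 0), c(2.2, 1.2, 0.6),
                           c(2.0, 2.4, 0.6), c(1.6, -0.9, 1.1))),
    GLU = list(name = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
               xyz = rbind(c(0, 0, 0), c(1.4, 0.2, 0), c(2.2, 1.2, 0.6),
                           c(2.0, 2.4, 0.6), c(1.7, -1.0, 1.1),
                           c(2.1, -2.3, 0.7), c(2.5, -3.3, 1.7),
                           c(2.6, -4.5, 1.3), c(2.8, -3.0, 2.9))),
    LYS = list(name = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
               xyz = rbind(c(0, 0, 0), c(1.4, 0.2, 0), c(2.2, 1.2, 0.6),
                           c(2.0, 2.4, 0.6), c(1.7, -1.0, 1.1),
                           c(2.1, -2.3, 0.7), c(2.6, -3.3, 1.7),
                           c(3.0, -4.6, 1.2), c(3.5, -5.5, 2.2))))
  base[[res_name]]
}

# linear chain of residues along x, 4 A apart per residue
make_protein_topology <- function(res_names, chain = "A", start_res = 1L,
                                  spacing = 4) {
  rows <- list(); coords <- list(); serial <- 0L
  for (i in seq_along(res_names)) {
    tpl <- res_template(res_names[i])
    off <- c((i - 1L) * spacing, 0, 0)
    for (a in seq_along(tpl$name)) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = tpl$name[a], residue_name = res_names[i],
        chain_id = chain, residue_number = start_res + i - 1L,
        element = substr(tpl$name[a], 1, 1), stringsAsFactors = FALSE)
      coords[[serial]] <- tpl$xyz[a, ] + off
    }
  }
  list(topology = do.call(rbind, rows), coords = do.call(rbind, coords))
}

make_protein_traj <- function(res_names = c("GLU", "GLY", "LYS", "ALA"),
                              n_frames = 1L, jitter = 0, seed = 1L, ...) {
  pt <- make_protein_topology(res_names, ...)
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(t)
    pt$coords + if (jitter > 0)
      matrix(rnorm(length(pt$coords), sd = jitter), nrow(pt$coords)) else 0)
  trajectory(pt$topology, frames)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# --- quaternion (Horn) superposition oracle ---------------------------------

rmsd_quaternion_oracle <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(A, B)   # S[a,b] = sum_i A_ia * B_ib
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# --- brute-force simple-path enumeration oracle -----------------------------

enumerate_simple_paths <- function(edges, source, sink) {
  adj <- list()
  for (k in seq_len(nrow(edges))) {
    f <- edges$from[k]; t <- edges$to[k]; w <- edges$weight[k]
    adj[[f]] <- rbind(adj[[f]], data.frame(to = t, w = w))
    adj[[t]] <- rbind(adj[[t]], data.frame(to = f, w = w))
  }
  out <- list()
  recurse <- function(path, w) {
    u <- path[length(path)]
    if (u == sink) {
      out[[length(out) + 1L]] <<- list(nodes = path, weight = w)
      return()
    }
    nb <- adj[[u]]
    if (is.null(nb)) return()
    for (e in seq_len(nrow(nb)))
      if (!(nb$to[e] %in% path)) recurse(c(path, nb$to[e]), w + nb$w[e])
  }
  recurse(source, 0)
  out
}

random_test_graph <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- paste("A", seq_len(n_nodes))
  pairs <- t(combn(n_nodes, 2))
  keep <- runif(nrow(pairs)) < 0.45
  edges <- data.frame(from = nodes[pairs[keep, 1]],
                      to = nodes[pairs[keep, 2]],
                      weight = round(runif(sum(keep), 0.1, 2), 3),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

path_key <- function(p) paste(p$nodes, collapse = ">")

# --- Fisher exact two-sided oracle (hypergeometric tail sum) ----------------

fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0L, k - n2); hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- spherical-cap buried-area oracle ---------------------------------------

# buried interface area of two overlapping spheres of expanded radii R1, R2
# at centre distance d: mean of the two cap areas removed from the union SASA
cap_bsa_oracle <- function(R1, R2, d) {
  if (d >= R1 + R2) return(0)
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  h1 <- R1 - x1
  h2 <- R2 - (d - x1)
  (2 * pi * R1 * h1 + 2 * pi * R2 * h2) / 2
}
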