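# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the package code paths.

# rank by repeated extraction of the current best (worst-case quadratic),
# independent of order()-based ranking
naive_rank_oracle <- function(scores, direction = "lower_is_better") {
  ids <- names(scores)
  s <- if (direction == "lower_is_better") scores else -scores
  out <- character(0)
  while (length(s)) {
    best <- min(s)
    cand <- sort(names(s)[s == best]) # tie: ascending id
    out <- c(out, cand[1])
    s <- s[setdiff(names(s), cand[1])]
  }
  out
}

# direct double-loop footrule over the union, using match()
footrule_oracle <- function(items1, items2) {
  u <- union(items1, items2)
  total <- 0
  for (t in u) {
    r1 <- match(t, items1); if (is.na(r1)) r1 <- length(items1) + 1
    r2 <- match(t, items2); if (is.na(r2)) r2 <- length(items2) + 1
    total <- total + abs(r1 - r2)
  }
  total
}

# second, independent permutation enumerator (insertion-based, unlike the
# package's first-element recursion)
perms_by_insertion <- function(n) {
  if (n == 1) return(list(1L))
  shorter <- perms_by_insertion(n - 1L)
  out <- list()
  for (p in shorter) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# exhaustive Phi minimisation by the insertion enumerator + objective_phi
brute_phi_oracle <- function(ensemble, cfg = distance_config()) {
  u <- sort(unique(unlist(lapply(ensemble$lists, function(l) l$items))))
  best <- Inf
  for (p in perms_by_insertion(length(u))) {
    cand <- ranked_list(u[p], name = "cand")
    phi <- objective_phi(cand, ensemble, cfg)
    if (phi < best) best <- phi
  }
  best
}

random_ranked_list <- function(n, name = "L", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(n))
  ranked_list(sample(ids), name = name)
}

# independent rigid-motion generator for invariance tests
oracle_random_rotation <- function() {
  repeat {
    M <- matrix(rnorm(9), 3, 3)
    qrd <- qr(M)
    Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
    if (abs(det(Q) - 1) < 1e-8) return(Q)
    if (det(Q) < 0) { Q[, 3] <- -Q[, 3]; return(Q) }
  }
}

transform_feature_molecule <- function(mol, rotation, translation) {
  xyz <- as.matrix(mol$points[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
  pts <- mol$points
  pts[, c("x", "y", "z")] <- xyz
  feature_molecule(mol$id, pts)
}

# Brute-force pharmacophore assignment oracle: enumerate every injective
# mapping of model features to type-compatible points (including skipped
# features down to min_features_required) with NO distance pruning, and test
# acceptance with an independently written superposition.
oracle_kabsch_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  A <- sweep(P, 2, cp); B <- sweep(Q, 2, cq)
  sv <- svd(t(A) %*% B)
  D <- diag(c(1, 1, sign(det(sv$v) * det(sv$u))))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- sweep(A %*% t(R), 2, cq, "+")
  list(moved = moved, rotation = R,
       translation = cq - as.numeric(R %*% cp))
}

oracle_match <- function(points, model, atoms = NULL) {
  if (is.null(atoms)) atoms <- as.matrix(points[, c("x", "y", "z")])
  k <- length(model$features)
  centers <- t(sapply(model$features, function(f) f$center))
  tols <- sapply(model$features, function(f) f$tolerance)
  base_of <- function(types) {
    unique(ifelse(types == "Acc2", "Acc", ifelse(types == "Don2", "Don", types)))
  }
  compat <- lapply(seq_len(k), function(j) {
    which(points$type %in% base_of(model$features[[j]]$allowed_types))
  })
  pxyz <- as.matrix(points[, c("x", "y", "z")])
  best_cnt <- 0L
  feats_sets <- unlist(lapply(model$min_features_required:k, function(sz) {
    utils::combn(seq_len(k), sz, simplify = FALSE)
  }), recursive = FALSE)
  for (feats in feats_sets) {
    grids <- compat[feats]
    if (any(lengths(grids) == 0)) next
    combos <- do.call(expand.grid, grids)
    for (ri in seq_len(nrow(combos))) {
      pts_idx <- as.integer(combos[ri, ])
      if (anyDuplicated(pts_idx)) next
      fit <- oracle_kabsch_rmsd(pxyz[pts_idx, , drop = FALSE],
                                centers[feats, , drop = FALSE])
      dev <- sqrt(rowSums((fit$moved - centers[feats, , drop = FALSE])^2))
      if (any(dev > tols[feats] + 1e-9)) next
      heavy <- sweep(atoms %*% t(fit$rotation), 2, fit$translation, "+")
      viol <- FALSE
      for (v in model$excluded_volumes) {
        if (any(sqrt(rowSums(sweep(heavy, 2, v$center)^2)) < v$radius - 1e-9)) {
          viol <- TRUE; break
        }
      }
      if (viol) next
      if (length(feats) > best_cnt) best_cnt <- length(feats)
    }
  }
  list(hit = best_cnt >= model$min_features_required, count = best_cnt)
}

# minimal V2000 SDF text for chemistry smoke tests
sdf_text <- function(title, atoms, bonds) {
  n_at <- nrow(atoms); n_bd <- if (is.null(bonds)) 0 else nrow(bonds)
  lines <- c(title, "  test", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_at, n_bd))
  for (i in seq_len(n_at)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              atoms$x[i], atoms$y[i], atoms$z[i], atoms$elem[i]))
  }
  if (n_bd > 0) {
    for (i in seq_len(n_bd)) {
      lines <- c(lines, sprintf("%3d%3d%3d  0", bonds$a[i], bonds$b[i], bonds$order[i]))
    }
  }
  c(lines, "M  END", "$$$$")
}

read_sdf_fixture <- function(lines) {
  f <- tempfile(fileext = ".sdf")
  writeLines(lines, f)
  on.exit(unlink(f))
  ChemmineR::read.SDFset(f)[[1]]
}

benzene_sdf <- function() {
  ang <- seq(0, by = pi / 3, length.out = 6)
  read_sdf_fixture(sdf_text(
    "benzene",
    data.frame(elem = rep("C", 6), x = 1.395 * cos(ang),
               y = 1.395 * sin(ang), z = 0),
    data.frame(a = 1:6, b = c(2:6, 1), order = rep(c(2, 1), 3))))
}

methanol_sdf <- function() {
  read_sdf_fixture(sdf_text(
    "methanol",
    data.frame(elem = c("C", "O"), x = c(0, 1.43), y = c(0, 0),
               z = c(0, 0.1)),
    data.frame(a = 1, b = 2, order = 1)))
}

# a molecule whose typed points coincide exactly with the model features
exact_hit_molecule <- function(model, id = "exact") {
  pts <- do.call(rbind, lapply(model$features, function(f) {
    base <- ifelse(f$allowed_types[1] == "Acc2", "Acc",
                   ifelse(f$allowed_types[1] == "Don2", "Don",
                          f$allowed_types[1]))
    data.frame(type = base, x = f$center[1], y = f$center[2], z = f$center[3])
  }))
  feature_molecule(id, pts)
}
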