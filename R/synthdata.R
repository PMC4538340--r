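#' Specification of a correlated synthetic scorer ensemble
#'
#' Generative model for docking-scorer ensembles used throughout the test
#' harness: a latent true affinity `u_t ~ N(0,1)` per item, and per scorer k
#' an emitted energy-like score
#' \deqn{s_k(t) = -\alpha_k u_t + \beta_{g(k)} g_{group}(t) + \epsilon_{kt},}
#' lower = better. `alpha_k` is the scorer's signal weight, `epsilon` its
#' private Gaussian noise (sd `sigma_k`), and scorers sharing a redundancy
#' group additionally share a group noise field with weight `beta_g` — two
#' scorers in one group with large `beta` are near-duplicates (redundant
#' views), while scorers with independent noise are complementary views of
#' the same latent affinity.
#'
#' @param n_items number of compounds.
#' @param n_scorers number of scoring functions.
#' @param alpha per-scorer signal weight(s) >= 0, recycled; at least one must
#'   be positive.
#' @param sigma per-scorer private noise sd(s) > 0, recycled.
#' @param groups list of integer vectors partitioning (a subset of) scorer
#'   indices into redundancy groups.
#' @param beta shared-noise weight per group, recycled over `groups`.
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_ensemble_spec`.
#' @export
synthetic_ensemble_spec <- function(n_items = 40L, n_scorers = 4L,
                                    alpha = 0.5, sigma = 1,
                                    groups = list(), beta = numeric(0),
                                    seed) {
  if (missing(seed) || !is.finite(seed)) stop("a seed is required")
  if (n_items < 2L) stop("n_items must be >= 2")
  if (n_scorers < 1L) stop("n_scorers must be >= 1")
  alpha <- rep(alpha, length.out = n_scorers)
  sigma <- rep(sigma, length.out = n_scorers)
  if (any(alpha < 0)) stop("alpha must be >= 0")
  if (all(alpha == 0)) {
    warning("all scorers have alpha = 0: scores carry no signal and the ",
            "reference ordering is meaningful only as a random baseline")
  }
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (length(groups)) {
    beta <- rep(beta, length.out = length(groups))
    idx <- unlist(groups)
    if (any(idx < 1 | idx > n_scorers) || anyDuplicated(idx)) {
      stop("groups must be disjoint subsets of scorer indices")
    }
    if (any(beta < 0)) stop("beta must be >= 0")
  }
  structure(
    list(n_items = as.integer(n_items), n_scorers = as.integer(n_scorers),
         alpha = alpha, sigma = sigma, groups = groups, beta = beta,
         seed = as.integer(seed)),
    class = "synthetic_ensemble_spec"
  )
}

#' Generate a synthetic scorer ensemble
#'
#' Draws a score table, the matching activity reference and the latent
#' affinities from a [synthetic_ensemble_spec()]. The reference ranks items
#' by latent affinity (best = largest `u`); the stored activity values are
#' EC50-like, `10 * exp(-u)` uM, so that lower activity = more potent and the
#' reference ordering is consistent with its activities.
#'
#' @param spec a [synthetic_ensemble_spec()].
#' @return list with elements `table` (a [score_table()], lower_is_better),
#'   `reference` (a [reference_rank()]), and `latent` (named numeric vector
#'   of true affinities).
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_ensemble_spec"))
  set.seed(spec$seed)
  n <- spec$n_items
  m <- spec$n_scorers
  ids <- sprintf("cpd_%03d", seq_len(n))
  u <- stats::setNames(stats::rnorm(n), ids)
  group_of <- rep(NA_integer_, m)
  for (g in seq_along(spec$groups)) group_of[spec$groups[[g]]] <- g
  gnoise <- if (length(spec$groups)) {
    matrix(stats::rnorm(n * length(spec$groups)), n, length(spec$groups))
  } else {
    matrix(0, n, 0)
  }
  values <- matrix(0, n, m,
                   dimnames = list(ids, sprintf("S%d", seq_len(m))))
  for (k in seq_len(m)) {
    shared <- if (!is.na(group_of[k])) {
      spec$beta[group_of[k]] * gnoise[, group_of[k]]
    } else 0
    values[, k] <- -spec$alpha[k] * u + shared + stats::rnorm(n, sd = spec$sigma[k])
  }
  list(table = score_table(values, directions = "lower_is_better"),
       reference = reference_rank(10 * exp(-u), name = "EC50"),
       latent = u)
}

#' A complementary-plus-redundant four-scorer study design
#'
#' Convenience spec for the headline synthetic experiment: three
#' complementary scorers (`S1`, `S2`, `S3`; equal signal weight
#' `alpha = 0.5`, independent unit noise) plus `S4`, a near-duplicate of `S3`
#' (the two share a group noise field with `beta = 1` and keep only small
#' private noise, sd 0.15). Aggregating the complementary trio should beat
#' any single scorer, and subsets containing both members of the redundant
#' pair double-count the shared noise and underperform.
#'
#' @param seed integer RNG seed.
#' @param n_items number of compounds; defaults to 107, the scale of the
#'   published EC50 benchmark this design emulates.
#' @return a [synthetic_ensemble_spec()].
#' @export
complementary_redundant_spec <- function(seed, n_items = 107L) {
  synthetic_ensemble_spec(
    n_items = n_items, n_scorers = 4L,
    alpha = 0.5, sigma = c(1, 1, 0.15, 0.15),
    groups = list(c(3L, 4L)), beta = 1,
    seed = seed
  )
}

# uniform point inside a sphere
runif_sphere <- function(center, radius) {
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  center + v * radius * stats::runif(1)^(1 / 3)
}

random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  d <- sign(diag(qr.R(qr_res)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigid_transform_points <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, translation, "+")
}

#' Generate a pharmacophore fixture library with known truth
#'
#' Builds abstract point-set "molecules" for pharmacophore-engine testing:
#' planted hits place one type-compatible feature point inside each model
#' feature's tolerance sphere and then apply a random rigid motion, so a
#' matching assignment exists by construction. Decoys violate the model in
#' one recorded way: `wrong_type` (one point's type incompatible with its
#' feature), `displaced` (one point moved far outside every feature sphere)
#' or `excluded_volume` (an extra heavy atom planted at an excluded-volume
#' centre, on an otherwise exact-geometry pose so the violation survives
#' superposition). Requires the model's feature spheres to be pairwise disjoint so
#' that violations are unambiguous; overlapping spheres are rejected as an
#' impossible geometry.
#'
#' @param n_hits,n_decoys library composition.
#' @param model a [pharmacophore_model()].
#' @param seed integer RNG seed.
#' @param decoy_classes violation classes to cycle through.
#' @return list with `molecules` (list of [feature_molecule()]) and `labels`
#'   (data frame `id`, `truth` logical, `class`).
#' @export
generate_screen_fixtures <- function(n_hits, n_decoys, model, seed,
                                     decoy_classes = c("wrong_type",
                                                       "displaced",
                                                       "excluded_volume")) {
  stopifnot(inherits(model, "pharmacophore_model"))
  if (missing(seed) || !is.finite(seed)) stop("a seed is required")
  k <- length(model$features)
  centers <- t(vapply(model$features, function(f) f$center, numeric(3)))
  tols <- vapply(model$features, function(f) f$tolerance, numeric(1))
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (sqrt(sum((centers[i, ] - centers[j, ])^2)) <= tols[i] + tols[j]) {
          stop("impossible geometry: feature tolerance spheres ", i, " and ",
               j, " overlap; fixtures need pairwise disjoint features")
        }
      }
    }
  }
  all_base <- c("Hyd", "Acc", "Don", "ARO")
  set.seed(seed)

  # Hit jitter is bounded by 0.9/sqrt(k) of each tolerance: the least-squares
  # superposition can only lower the total squared deviation below the
  # planted pose's, so every per-point deviation stays below
  # sqrt(k) * 0.9/sqrt(k) * tol < tol and a matching assignment is
  # guaranteed to be accepted.
  make_hit_points <- function(jitter = 0.9 / sqrt(k)) {
    pts <- lapply(seq_len(k), function(j) {
      types <- base_feature_types(model$features[[j]]$allowed_types)
      p <- if (jitter > 0) {
        runif_sphere(centers[j, ], jitter * tols[j])
      } else {
        centers[j, ]
      }
      data.frame(type = sample(types, 1), x = p[1], y = p[2], z = p[3])
    })
    do.call(rbind, pts)
  }
  transform_mol <- function(pts) {
    xyz <- rigid_transform_points(as.matrix(pts[, c("x", "y", "z")]),
                                  random_rotation(),
                                  stats::runif(3, -20, 20))
    pts[, c("x", "y", "z")] <- xyz
    pts
  }

  mols <- list()
  labels <- list()
  for (h in seq_len(n_hits)) {
    id <- sprintf("hit_%03d", h)
    mols[[id]] <- feature_molecule(id, transform_mol(make_hit_points()))
    labels[[id]] <- data.frame(id = id, truth = TRUE, class = "hit")
  }
  if (n_decoys > 0 && length(model$excluded_volumes) == 0L) {
    decoy_classes <- setdiff(decoy_classes, "excluded_volume")
    if (!length(decoy_classes)) {
      stop("excluded_volume decoys requested but the model has no excluded volumes")
    }
  }
  for (d in seq_len(n_decoys)) {
    cls <- decoy_classes[((d - 1L) %% length(decoy_classes)) + 1L]
    # excluded-volume decoys use exact feature-centre geometry: the
    # superposition then reproduces the planted pose exactly, so the extra
    # atom is guaranteed to sit at the excluded-volume centre (a jittered
    # pose would let the fit's rotational residual swing a distant atom off
    # the sphere)
    pts <- make_hit_points(jitter = if (cls == "excluded_volume") 0 else
                                      0.9 / sqrt(k))
    if (cls == "wrong_type") {
      j <- sample.int(k, 1)
      allowed <- base_feature_types(model$features[[j]]$allowed_types)
      bad <- setdiff(all_base, allowed)
      if (!length(bad)) cls <- "displaced" else pts$type[j] <- sample(bad, 1)
    }
    if (cls == "displaced") {
      j <- sample.int(k, 1)
      repeat {
        dir <- stats::rnorm(3)
        p <- centers[j, ] + 5 * tols[j] * dir / sqrt(sum(dir^2))
        inside <- any(sqrt(colSums((t(centers) - p)^2)) <= tols)
        if (!inside) break
      }
      pts[j, c("x", "y", "z")] <- p
    }
    if (cls == "excluded_volume") {
      v <- model$excluded_volumes[[sample.int(length(model$excluded_volumes), 1)]]
      pts <- rbind(pts, data.frame(type = "Hyd", x = v$center[1],
                                   y = v$center[2], z = v$center[3]))
    }
    id <- sprintf("decoy_%03d", d)
    mols[[id]] <- feature_molecule(id, transform_mol(pts))
    labels[[id]] <- data.frame(id = id, truth = FALSE, class = cls)
  }
  list(molecules = mols, labels = do.call(rbind, c(labels, list(make.row.names = FALSE))))
}
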