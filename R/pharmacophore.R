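#' @useDynLib dra, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

PHARMACOPHORE_TYPES <- c("Hyd", "Acc", "Acc2", "Don", "Don2", "ARO")

# Acc2/Don2 are projected/extended acceptor-donor variants; chemically they
# map onto the same detected points and are distinct only as model-side type
# labels. Collapsing them gives the base types a detected point can carry.
base_feature_types <- function(types) {
  unique(ifelse(types == "Acc2", "Acc", ifelse(types == "Don2", "Don", types)))
}

#' 3D pharmacophore models
#'
#' A pharmacophore model is a set of typed feature spheres — each a centre in
#' Angstrom coordinates, a tolerance radius, and the set of chemical feature
#' types allowed to satisfy it (`Hyd` hydrophobe, `Acc`/`Acc2` H-bond
#' acceptor and its projected variant, `Don`/`Don2` donor, `ARO` aromatic
#' ring) — plus excluded-volume spheres that no heavy atom of a matched
#' conformer may penetrate. `min_features_required` allows partial matches;
#' it defaults to all features (a molecule must fit the full template) and
#' may not be below 3, the minimum for a meaningful rigid 3D match.
#'
#' @param features list of features, each `list(allowed_types =, center =,
#'   tolerance =)` with a length-3 numeric centre and tolerance > 0.
#' @param excluded_volumes list of `list(center =, radius =)` spheres.
#' @param min_features_required integer in `3..length(features)`.
#' @return an object of class `pharmacophore_model`.
#' @export
pharmacophore_model <- function(features, excluded_volumes = list(),
                                min_features_required = length(features)) {
  if (length(features) < 3L) stop("a pharmacophore model needs >= 3 features")
  features <- lapply(features, function(f) {
    if (is.null(f$allowed_types) || !length(f$allowed_types)) {
      stop("every feature needs a non-empty allowed_types set")
    }
    bad <- setdiff(f$allowed_types, PHARMACOPHORE_TYPES)
    if (length(bad)) stop("unknown feature type(s): ", paste(bad, collapse = ", "))
    if (length(f$center) != 3L || any(!is.finite(f$center))) {
      stop("feature centers must be finite 3D coordinates")
    }
    if (is.null(f$tolerance) || f$tolerance <= 0) {
      stop("feature tolerances must be > 0")
    }
    list(allowed_types = as.character(f$allowed_types),
         center = as.numeric(f$center), tolerance = as.numeric(f$tolerance))
  })
  excluded_volumes <- lapply(excluded_volumes, function(v) {
    if (length(v$center) != 3L || any(!is.finite(v$center)) ||
        is.null(v$radius) || v$radius <= 0) {
      stop("excluded volumes need a finite 3D center and radius > 0")
    }
    list(center = as.numeric(v$center), radius = as.numeric(v$radius))
  })
  if (min_features_required < 3L || min_features_required > length(features)) {
    stop("min_features_required must lie in 3..", length(features))
  }
  structure(
    list(features = features, excluded_volumes = excluded_volumes,
         min_features_required = as.integer(min_features_required),
         version = "1.0"),
    class = "pharmacophore_model"
  )
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat(sprintf("<pharmacophore_model> %d features (min match %d), %d excluded volumes\n",
              length(x$features), x$min_features_required,
              length(x$excluded_volumes)))
  for (i in seq_along(x$features)) {
    f <- x$features[[i]]
    cat(sprintf("  F%d %-14s @ (%.2f, %.2f, %.2f) r=%.2f\n", i,
                paste(f$allowed_types, collapse = "|"),
                f$center[1], f$center[2], f$center[3], f$tolerance))
  }
  invisible(x)
}

#' Read / write a pharmacophore model (JSON)
#'
#' Schema: `{"version": "1.0", "features": [{"types": [...], "center":
#' [x,y,z], "tolerance": r}, ...], "excluded_volumes": [{"center": [x,y,z],
#' "radius": r}, ...], "min_features_required": k}`.
#'
#' @param path JSON file path.
#' @return `read_pharmacophore_model()` returns a [pharmacophore_model()].
#' @export
read_pharmacophore_model <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(js$features)) stop("no 'features' array in ", path)
  feats <- lapply(js$features, function(f) {
    list(allowed_types = unlist(f$types), center = unlist(f$center),
         tolerance = f$tolerance)
  })
  evs <- lapply(js$excluded_volumes, function(v) {
    list(center = unlist(v$center), radius = v$radius)
  })
  k <- if (is.null(js$min_features_required)) length(feats) else js$min_features_required
  pharmacophore_model(feats, evs, min_features_required = k)
}

#' @param model a [pharmacophore_model()] to write.
#' @rdname read_pharmacophore_model
#' @export
write_pharmacophore_model <- function(model, path) {
  js <- list(
    version = model$version,
    features = lapply(model$features, function(f) {
      list(types = f$allowed_types, center = f$center, tolerance = f$tolerance)
    }),
    excluded_volumes = lapply(model$excluded_volumes, function(v) {
      list(center = v$center, radius = v$radius)
    }),
    min_features_required = model$min_features_required
  )
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Abstract point-set molecules
#'
#' A `feature_molecule` is a pre-typed 3D point set standing in for a real
#' conformer: each point carries a feature type and coordinates, and all
#' points double as heavy atoms for the excluded-volume test. Used as exact,
#' chemistry-free fixtures for the matching engine.
#'
#' @param id molecule identifier.
#' @param points data frame with columns `type`, `x`, `y`, `z`.
#' @return an object of class `feature_molecule`.
#' @export
feature_molecule <- function(id, points) {
  stopifnot(is.data.frame(points),
            all(c("type", "x", "y", "z") %in% names(points)))
  bad <- setdiff(points$type, c("Hyd", "Acc", "Don", "ARO"))
  if (length(bad)) stop("point types must be base types; got: ",
                        paste(bad, collapse = ", "))
  structure(list(id = as.character(id),
                 points = points[, c("type", "x", "y", "z")]),
            class = "feature_molecule")
}

#' Detect typed pharmacophore feature points on a conformer
#'
#' Generic feature perception. For [feature_molecule()] fixtures the declared
#' points are returned as-is. For an SDF conformer (a `ChemmineR::SDF`
#' object, explicit 3D coordinates) the shipped typing rules are:
#' * `Acc`: every N or O atom;
#' * `Don`: N/O atoms bearing an explicit hydrogen, or with fewer heavy
#'   neighbours than their usual valence (so a hydroxyl oxygen in an SDF
#'   without explicit hydrogens still donates);
#' * `ARO`: one point per aromatic ring, at the ring centroid;
#' * `Hyd`: one point per connected fragment of carbon atoms having no
#'   heteroatom neighbour, at the fragment centroid.
#'
#' @param mol a [feature_molecule()] or a `ChemmineR` `SDF` object.
#' @param ... unused.
#' @return data frame of feature points: `type`, `x`, `y`, `z`, `source`
#'   (atom indices, comma-separated).
#' @export
detect_features <- function(mol, ...) UseMethod("detect_features")

#' @export
detect_features.feature_molecule <- function(mol, ...) {
  out <- mol$points
  out$source <- as.character(seq_len(nrow(out)))
  out
}

#' @export
detect_features.SDF <- function(mol, ...) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("feature detection on SDF molecules requires the ChemmineR package")
  }
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elem <- gsub("_.*$", "", rownames(ab))
  xyz <- ab[, 1:3, drop = FALSE]
  if (all(xyz[, 3] == 0) && all(xyz[, 2] == 0)) {
    stop("molecule appears to lack 3D coordinates; generate conformers first")
  }
  n_atoms <- nrow(ab)
  adj <- vector("list", n_atoms)
  if (!is.null(bb) && nrow(bb)) {
    for (b in seq_len(nrow(bb))) {
      i <- bb[b, 1]; j <- bb[b, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  pts <- list()
  add_pt <- function(type, coords, src) {
    pts[[length(pts) + 1L]] <<- data.frame(
      type = type, x = coords[1], y = coords[2], z = coords[3],
      source = paste(src, collapse = ","))
  }
  usual_valence <- c(N = 3L, O = 2L)
  for (a in seq_len(n_atoms)) {
    if (elem[a] %in% c("N", "O")) {
      add_pt("Acc", xyz[a, ], a)
      nb <- adj[[a]]
      has_h <- any(elem[nb] == "H")
      heavy_deg <- sum(elem[nb] != "H")
      if (has_h || heavy_deg < usual_valence[[elem[a]]]) {
        add_pt("Don", xyz[a, ], a)
      }
    }
  }
  rings <- tryCatch(
    ChemmineR::rings(mol, type = "all", arom = TRUE, inner = TRUE),
    error = function(e) NULL)
  aro <- rings$AROMATIC
  ringlist <- rings$RINGS
  if (!is.null(ringlist) && length(ringlist)) {
    for (ri in seq_along(ringlist)) {
      if (!is.null(aro) && !isTRUE(aro[ri])) next
      atoms <- as.integer(gsub("[^0-9]", "", ringlist[[ri]]))
      add_pt("ARO", colMeans(xyz[atoms, , drop = FALSE]), atoms)
    }
  }
  is_hyd_c <- vapply(seq_len(n_atoms), function(a) {
    elem[a] == "C" && all(elem[adj[[a]]] %in% c("C", "H"))
  }, logical(1))
  seen <- rep(FALSE, n_atoms)
  for (a in which(is_hyd_c)) {
    if (seen[a]) next
    frag <- a; queue <- a; seen[a] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (!seen[nb] && is_hyd_c[nb]) {
          seen[nb] <- TRUE; frag <- c(frag, nb); queue <- c(queue, nb)
        }
      }
    }
    add_pt("Hyd", colMeans(xyz[frag, , drop = FALSE]), sort(frag))
  }
  if (!length(pts)) {
    return(data.frame(type = character(), x = numeric(), y = numeric(),
                      z = numeric(), source = character()))
  }
  do.call(rbind, pts)
}

# Least-squares rigid superposition (Kabsch): rotation R and translation t
# minimising sum ||R p + t - q||^2 over paired points P -> Q (rows).
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cq - as.numeric(R %*% cp)
  list(rotation = R, translation = t_vec)
}

apply_rigid <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
}

point_compatible <- function(point_type, allowed_types) {
  point_type %in% base_feature_types(allowed_types)
}

#' Match a typed point set against a pharmacophore model
#'
#' Searches assignments of distinct detected feature points to model
#' features with compatible types. Partial assignments are pruned by
#' inter-feature distance compatibility (`|d_points - d_model| <= tol_a +
#' tol_b` for every assigned pair). Each surviving assignment of size >=
#' `min_features_required` is superposed onto the model centres by
#' least-squares rigid fit; it is accepted when every assigned point falls
#' inside its feature's tolerance sphere after superposition and no heavy
#' atom of the aligned conformer lies strictly inside any excluded-volume
#' sphere. Among accepting assignments the one matching the most features
#' wins, ties broken by lowest RMSD.
#'
#' @param points data frame of typed feature points (`type`, `x`, `y`, `z`),
#'   e.g. from [detect_features()].
#' @param model a [pharmacophore_model()].
#' @param atoms optional matrix/data frame of heavy-atom coordinates for the
#'   excluded-volume test; defaults to the feature point coordinates.
#' @param id molecule identifier recorded in the result.
#' @return a `screen_result`: `id`, `hit`, `best_match` (data frame
#'   `feature` -> `point`), `matched_count`, `rmsd`, `conformer`.
#' @export
match_pharmacophore <- function(points, model, atoms = NULL, id = "molecule") {
  stopifnot(inherits(model, "pharmacophore_model"))
  if (!nrow(points)) stop("no feature points supplied")
  if (is.null(atoms)) atoms <- as.matrix(points[, c("x", "y", "z")])
  atoms <- as.matrix(atoms)
  k <- length(model$features)
  centers <- t(vapply(model$features, function(f) f$center, numeric(3)))
  tols <- vapply(model$features, function(f) f$tolerance, numeric(1))
  pxyz <- as.matrix(points[, c("x", "y", "z")])
  cand <- lapply(seq_len(k), function(j) {
    which(vapply(points$type, point_compatible, logical(1),
                 model$features[[j]]$allowed_types))
  })
  d_model <- as.matrix(stats::dist(centers))
  d_points <- as.matrix(stats::dist(pxyz))
  min_req <- model$min_features_required
  max_skip <- k - min_req

  best <- list(count = -1L, rmsd = Inf, assign = NULL)
  assign <- integer(k) # 0 = skipped
  search <- function(j, used, skipped) {
    if (j > k) {
      feats <- which(assign > 0L)
      if (length(feats) < min_req) return(invisible())
      fit <- kabsch(pxyz[assign[feats], , drop = FALSE],
                    centers[feats, , drop = FALSE])
      moved <- apply_rigid(pxyz[assign[feats], , drop = FALSE], fit)
      dev <- sqrt(rowSums((moved - centers[feats, , drop = FALSE])^2))
      if (any(dev > tols[feats] + 1e-9)) return(invisible())
      heavy <- apply_rigid(atoms, fit)
      for (v in model$excluded_volumes) {
        dd <- sqrt(rowSums(sweep(heavy, 2, v$center)^2))
        if (any(dd < v$radius - 1e-9)) return(invisible())
      }
      rmsd <- sqrt(mean(dev^2))
      cnt <- length(feats)
      if (cnt > best$count || (cnt == best$count && rmsd < best$rmsd)) {
        best <<- list(count = cnt, rmsd = rmsd, assign = assign)
      }
      return(invisible())
    }
    # try skipping feature j
    if (skipped < max_skip) {
      assign[j] <<- 0L
      search(j + 1L, used, skipped + 1L)
    }
    for (p in cand[[j]]) {
      if (p %in% used) next
      ok <- TRUE
      for (jj in seq_len(j - 1L)) {
        if (assign[jj] == 0L) next
        if (abs(d_points[p, assign[jj]] - d_model[j, jj]) >
            tols[j] + tols[jj]) { ok <- FALSE; break }
      }
      if (!ok) next
      assign[j] <<- p
      search(j + 1L, c(used, p), skipped)
    }
    assign[j] <<- 0L
    invisible()
  }
  search(1L, integer(0), 0L)

  hit <- best$count >= min_req
  structure(
    list(id = id, hit = hit,
         best_match = if (hit) {
           feats <- which(best$assign > 0L)
           data.frame(feature = feats, point = best$assign[feats])
         } else {
           data.frame(feature = integer(), point = integer())
         },
         matched_count = if (hit) best$count else 0L,
         rmsd = if (hit) best$rmsd else NA_real_,
         conformer = NA_integer_),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s: %s (matched %d, RMSD %s)\n", x$id,
              if (x$hit) "HIT" else "miss", x$matched_count,
              if (is.na(x$rmsd)) "-" else sprintf("%.3f A", x$rmsd)))
  invisible(x)
}

#' Screen a molecule library against a pharmacophore model
#'
#' Runs [detect_features()] and [match_pharmacophore()] over a library. A
#' molecule is a hit if any of its conformers matches. Accepted inputs: a
#' list of [feature_molecule()] fixtures, a `ChemmineR` `SDFset` with 3D
#' coordinates, or a path to an SDF file / a character vector of SMILES
#' (SMILES trigger single-conformer 3D generation through the `obabel`
#' command-line tool, recorded in the attributes). Unparseable records are
#' skipped and counted, not fatal.
#'
#' @param molecules library (see above).
#' @param model a [pharmacophore_model()].
#' @param seed seed recorded for conformer generation.
#' @return data frame of screen results (`id`, `hit`, `matched_count`,
#'   `rmsd`), input order, with attributes `n_skipped` and `seed`; the full
#'   `screen_result` objects are in attribute `results`.
#' @export
screen_library <- function(molecules, model, seed = 1L) {
  stopifnot(inherits(model, "pharmacophore_model"))
  if (is.character(molecules)) {
    if (length(molecules) == 1L && file.exists(molecules)) {
      if (!requireNamespace("ChemmineR", quietly = TRUE)) {
        stop("reading SDF libraries requires the ChemmineR package")
      }
      molecules <- ChemmineR::read.SDFset(molecules)
    } else {
      molecules <- smiles_to_sdfset(molecules, seed = seed)
    }
  }
  if (inherits(molecules, "SDFset")) {
    ids <- ChemmineR::sdfid(molecules)
    molecules <- stats::setNames(
      lapply(seq_along(molecules), function(i) molecules[[i]]), ids)
  }
  n_skipped <- 0L
  results <- vector("list", length(molecules))
  for (i in seq_along(molecules)) {
    mol <- molecules[[i]]
    id <- if (inherits(mol, "feature_molecule")) mol$id
          else if (!is.null(names(molecules))) names(molecules)[i]
          else sprintf("mol_%03d", i)
    res <- tryCatch({
      pts <- detect_features(mol)
      if (!nrow(pts)) {
        structure(list(id = id, hit = FALSE,
                       best_match = data.frame(feature = integer(),
                                               point = integer()),
                       matched_count = 0L, rmsd = NA_real_,
                       conformer = NA_integer_),
                  class = "screen_result")
      } else {
        atoms <- if (inherits(mol, "SDF")) {
          ab <- ChemmineR::atomblock(mol)
          ab[gsub("_.*$", "", rownames(ab)) != "H", 1:3, drop = FALSE]
        } else NULL
        match_pharmacophore(pts, model, atoms = atoms, id = id)
      }
    }, error = function(e) {
      n_skipped <<- n_skipped + 1L
      NULL
    })
    results[[i]] <- res
  }
  keep <- !vapply(results, is.null, logical(1))
  results <- results[keep]
  df <- data.frame(
    id = vapply(results, `[[`, character(1), "id"),
    hit = vapply(results, `[[`, logical(1), "hit"),
    matched_count = vapply(results, `[[`, integer(1), "matched_count"),
    rmsd = vapply(results, `[[`, numeric(1), "rmsd")
  )
  attr(df, "n_skipped") <- n_skipped
  attr(df, "seed") <- seed
  attr(df, "results") <- results
  df
}

# SMILES -> single 3D conformer each, via the obabel CLI (--gen3d).
smiles_to_sdfset <- function(smiles, seed = 1L) {
  if (!nzchar(Sys.which("obabel"))) {
    stop("SMILES input needs the obabel command-line tool for 3D generation")
  }
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("SMILES input requires the ChemmineR package")
  }
  smi <- tempfile(fileext = ".smi")
  sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(smi, sdf)), add = TRUE)
  ids <- if (!is.null(names(smiles))) names(smiles) else
    sprintf("mol_%03d", seq_along(smiles))
  writeLines(paste(smiles, ids), smi)
  system2("obabel", c(smi, "-O", sdf, "--gen3d"), stdout = FALSE,
          stderr = FALSE)
  ChemmineR::read.SDFset(sdf)
}

#' The shipped template pharmacophore (synthetic geometry)
#'
#' A five-feature model carrying the PXR screening type signature
#' (Hyd|Acc, Acc|Acc2|Don2, Hyd|Acc2, Hyd|Acc, ARO|Hyd) with eight excluded
#' volumes. The geometry is synthetic placeholder geometry — well-separated
#' centres suitable for fixtures and demonstrations — not coordinates fitted
#' to any receptor; real screens should load a measured model via
#' [read_pharmacophore_model()].
#'
#' @return a [pharmacophore_model()].
#' @export
example_pharmacophore_model <- function() {
  read_pharmacophore_model(
    system.file("extdata", "pxr_template_synthetic.json", package = "dra",
                mustWork = TRUE))
}
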