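#' Cross-section shape features by PCA
#'
#' Interpolates all cross-section profiles to a common length, centres them
#' around the mean profile, and extracts the first principal components as
#' unsupervised canal shape features (feature 1 typically captures the mean
#' area difference, feature 2 a localized pre-ampullary constriction).
#'
#' @param profiles a list of profiles — numeric area vectors, `cs_profile`
#'   objects, or two-column tibbles (`s`, `area`) — optionally named by
#'   animal.
#' @param n_components number of features to return (default 5).
#' @param n_points common interpolation length.
#' @return A `cs_features` object: `$scores` (animal x feature tibble),
#'   `$components` (long tibble `s`, `component`, `value`),
#'   `$variance_fraction`. [tidy()] returns the component shapes.
#' @export
cs_features <- function(profiles, n_components = 5, n_points = 200) {
  if (length(profiles) <= n_components) {
    abort(sprintf("need more than %d profiles for %d components",
                  n_components, n_components),
          class = "gazestab_rank_error")
  }
  nm <- names(profiles)
  if (is.null(nm)) nm <- paste0("animal_", seq_along(profiles))
  as_vec <- function(p) {
    if (inherits(p, "cs_profile") || is.data.frame(p)) {
      approx(seq(0, 1, length.out = nrow(p)), p$area,
             xout = seq(0, 1, length.out = n_points))$y
    } else {
      approx(seq(0, 1, length.out = length(p)), p,
             xout = seq(0, 1, length.out = n_points))$y
    }
  }
  X <- do.call(rbind, lapply(profiles, as_vec))
  Xc <- sweep(X, 2, colMeans(X))
  if (sum(Xc^2) < 1e-10 * max(1, sum(X^2))) {
    abort("all profiles identical after centring; no shape variance to decompose",
          class = "gazestab_rank_error")
  }
  pc <- prcomp(Xc, center = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- align_signs(pc$rotation[, seq_len(k), drop = FALSE])
  scores <- Xc %*% rot
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  sc <- as_tibble(scores, .name_repair = ~ paste0("cs_feature_", seq_len(k)))
  sc <- bind_cols(tibble(animal = nm), sc)
  comps <- tidyr::pivot_longer(
    bind_cols(tibble(s = seq(0, 1, length.out = n_points)),
              as_tibble(rot, .name_repair = ~ paste0("cs_feature_", seq_len(k)))),
    -"s", names_to = "component", values_to = "value")
  structure(list(scores = sc, components = comps,
                 variance_fraction = varfrac[seq_len(k)],
                 mean_profile = colMeans(X)),
            class = "cs_features")
}

#' @export
print.cs_features <- function(x, ...) {
  cat(sprintf("<cs_features> %d animals, %d features (%.1f%% variance)\n",
              nrow(x$scores), length(x$variance_fraction),
              100 * sum(x$variance_fraction)))
  invisible(x)
}

#' @rdname cs_features
#' @param x a `cs_features` object.
#' @param ... unused.
#' @export
tidy.cs_features <- function(x, ...) x$components

# fix each component's sign so its largest-magnitude loading is positive
align_signs <- function(rot) {
  for (c in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, c]))
    if (rot[i, c] < 0) rot[, c] <- -rot[, c]
  }
  rot
}

#' Resample a cohort with missing measures
#'
#' Each animal's missing measures are imputed by drawing, with replacement,
#' from the observed values of that variable within the same species (the
#' most conservative assumption: variables independently drawn from their
#' species-level distributions). The draw is repeated `n_reps` times; every
#' replicate is then z-scored per variable. Observed entries are preserved
#' exactly in every replicate.
#'
#' @param cohort tibble with columns `animal_id`, `species`, and one numeric
#'   column per measure; missing entries are `NA`.
#' @param n_reps number of resampling replicates (default 10000).
#' @param seed integer seed.
#' @param donor `"species"` (default) restricts donor pools to the same
#'   species; `"all"` pools across the whole cohort.
#' @return A `resampled_cohort`: normalized replicate array
#'   (`rep x animal x variable`) plus per-replicate centres/scales, animal
#'   ids, species and variable names.
#' @export
resample_cohorts <- function(cohort, n_reps = 10000, seed = 1,
                             donor = c("species", "all")) {
  donor <- match.arg(donor)
  stopifnot(all(c("animal_id", "species") %in% names(cohort)))
  vars <- setdiff(names(cohort), c("animal_id", "species"))
  if (length(vars) == 0) abort("no measure columns", class = "gazestab_input_error")
  M <- as.matrix(cohort[vars])
  n_an <- nrow(M)
  species <- as.character(cohort$species)

  # coverage check: every variable observed in >= 1 animal per species
  uncovered <- character(0)
  for (v in vars) {
    for (sp in unique(species)) {
      pool <- M[species == sp, v]
      if (donor == "all") pool <- M[, v]
      if (all(is.na(pool))) uncovered <- c(uncovered, paste0(v, " (", sp, ")"))
    }
  }
  if (length(uncovered) > 0) {
    abort(paste0("variable(s) with no observed donor values: ",
                 paste(unique(uncovered), collapse = ", ")),
          class = "gazestab_coverage_error")
  }

  set.seed(seed)
  arr <- array(NA_real_, dim = c(n_reps, n_an, length(vars)),
               dimnames = list(NULL, cohort$animal_id, vars))
  for (v in seq_along(vars)) {
    col <- M[, v]
    base <- matrix(col, n_reps, n_an, byrow = TRUE)
    nas <- which(is.na(col))
    for (ai in nas) {
      pool <- if (donor == "species") col[species == species[ai] & !is.na(col)]
      else col[!is.na(col)]
      base[, ai] <- sample(pool, n_reps, replace = TRUE)
    }
    arr[, , v] <- base
  }
  centers <- apply(arr, c(1, 3), mean)
  scales <- apply(arr, c(1, 3), sd)
  scales[scales < 1e-12] <- 1
  norm <- arr
  for (v in seq_along(vars)) {
    norm[, , v] <- (arr[, , v] - centers[, v]) / scales[, v]
  }
  structure(list(normalized = norm, centers = centers, scales = scales,
                 animal_id = cohort$animal_id, species = species,
                 variables = vars, n_reps = n_reps, seed = seed,
                 donor = donor),
            class = "resampled_cohort")
}

#' @export
print.resampled_cohort <- function(x, ...) {
  cat(sprintf("<resampled_cohort> %d replicates x %d animals x %d variables (donor: %s)\n",
              x$n_reps, length(x$animal_id), length(x$variables), x$donor))
  invisible(x)
}

#' Average principal components over resampling replicates
#'
#' Runs a PCA on every normalized replicate, aligns component signs (largest
#' absolute loading positive — plain averaging is ill-defined up to sign),
#' averages the loadings, and re-orthonormalizes the average (polar
#' projection onto the nearest orthonormal frame).
#'
#' @param rs a `resampled_cohort`.
#' @param n_components number of components to keep (default: full rank).
#' @return An `avg_components` object: `$rotation` (variable x component),
#'   `$variance_fraction` (mean over replicates). [tidy()] returns a long
#'   loading tibble.
#' @export
average_components <- function(rs, n_components = NULL) {
  stopifnot(inherits(rs, "resampled_cohort"))
  dims <- dim(rs$normalized)
  n_reps <- dims[1]; n_an <- dims[2]; n_var <- dims[3]
  if (n_reps < 2) abort("need >= 2 replicates", class = "gazestab_input_error")
  k_full <- min(n_an - 1, n_var)
  k <- if (is.null(n_components)) k_full else min(n_components, k_full)
  acc <- matrix(0, n_var, k)
  vf <- numeric(k)
  for (r in seq_len(n_reps)) {
    X <- rs$normalized[r, , ]
    pc <- tryCatch(prcomp(X, center = FALSE),
                   error = function(e) abort("rank-deficient replicate",
                                             class = "gazestab_rank_error"))
    if (ncol(pc$rotation) < k) {
      abort("rank-deficient replicate", class = "gazestab_rank_error")
    }
    rot <- align_signs(pc$rotation[, seq_len(k), drop = FALSE])
    acc <- acc + rot
    tot <- sum(pc$sdev^2)
    vf <- vf + pc$sdev[seq_len(k)]^2 / tot
  }
  avg <- acc / n_reps
  sv <- svd(avg)
  orth <- sv$u %*% t(sv$v)
  orth <- align_signs(orth)
  rownames(orth) <- rs$variables
  colnames(orth) <- paste0("PC", seq_len(k))
  structure(list(rotation = orth, variance_fraction = vf / n_reps),
            class = "avg_components")
}

#' @export
print.avg_components <- function(x, ...) {
  cat(sprintf("<avg_components> %d components over %d variables; PC1 explains %.1f%%\n",
              ncol(x$rotation), nrow(x$rotation),
              100 * x$variance_fraction[1]))
  invisible(x)
}

#' @rdname average_components
#' @param x an `avg_components` object.
#' @param ... unused.
#' @export
tidy.avg_components <- function(x, ...) {
  as_tibble(x$rotation, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' Most representative resampled dataset
#'
#' Selects the replicate with the smallest elementwise sum of squared
#' differences to the mean replicate; ties go to the lowest replicate index.
#'
#' @param rs a `resampled_cohort`.
#' @return A `representative_dataset`: `$data` (animal x variable normalized
#'   matrix), `$replicate`, plus animal ids and species.
#' @export
representative_dataset <- function(rs) {
  stopifnot(inherits(rs, "resampled_cohort"))
  n_reps <- dim(rs$normalized)[1]
  mean_rep <- apply(rs$normalized, c(2, 3), mean)
  dists <- vapply(seq_len(n_reps), function(r) {
    sum((rs$normalized[r, , ] - mean_rep)^2)
  }, numeric(1))
  best <- which.min(dists)          # which.min takes the first on ties
  data <- rs$normalized[best, , ]
  dimnames(data) <- list(rs$animal_id, rs$variables)
  structure(list(data = data, replicate = best, distances = dists,
                 animal_id = rs$animal_id, species = rs$species),
            class = "representative_dataset")
}

#' Project animals onto average components
#'
#' Scores each animal's normalized measurement vector on the average
#' principal components by the dot product.
#'
#' @param dataset a `representative_dataset` (or a plain animal x variable
#'   matrix).
#' @param components an `avg_components` (or a variable x component matrix).
#' @return A tibble: `animal_id`, `species` (when known), one score column
#'   per component.
#' @export
project_cohort <- function(dataset, components) {
  X <- if (inherits(dataset, "representative_dataset")) dataset$data
  else as.matrix(dataset)
  R <- if (inherits(components, "avg_components")) components$rotation
  else as.matrix(components)
  if (ncol(X) != nrow(R)) {
    abort(sprintf("dimension mismatch: %d variables vs %d loadings",
                  ncol(X), nrow(R)), class = "gazestab_input_error")
  }
  S <- X %*% R
  out <- as_tibble(S, .name_repair = ~ colnames(R))
  out <- bind_cols(tibble(animal_id = rownames(X) %||% seq_len(nrow(X))), out)
  if (inherits(dataset, "representative_dataset")) {
    out <- bind_cols(out[1], tibble(species = dataset$species), out[-1])
  }
  out
}

#' Variance-scaled loading map
#'
#' Scales each component's loadings by its explained-variance fraction
#' (signs retained), the quantity mapped in a loading heat map: strong red =
#' strong positive covariance with the component, strong blue = negative.
#'
#' @param components an `avg_components`.
#' @return A tibble: `variable`, `component`, `loading`, `scaled` (loading x
#'   variance fraction).
#' @export
loading_map <- function(components) {
  stopifnot(inherits(components, "avg_components"))
  long <- tidy(components)
  vf <- tibble(component = colnames(components$rotation),
               variance_fraction = components$variance_fraction)
  long |>
    left_join(vf, by = "component") |>
    mutate(scaled = .data$loading * .data$variance_fraction) |>
    select("variable", "component", "loading", "scaled")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
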