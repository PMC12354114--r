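# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# Memoise an expensive fixture under a name.
fixture <- function(name, expr) {
  if (!exists(name, .fixture_env)) assign(name, force(expr), .fixture_env)
  get(name, .fixture_env)
}

# A textured phantom slice plus its preprocessed image and feature set.
phantom_features <- function(seed = 42L, z = 3L, perturbation = NULL,
                             akaze = akaze_params()) {
  id <- phantom_identity(seed)
  img <- render_slice(id, z, perturbation)
  extract_features(preprocess_slice(img, preprocess_params()), akaze)
}

default_slice_features <- function() {
  fixture("default_slice_features", phantom_features())
}

# Brute-force O(n^2) reference for one matching direction up to (and
# including) unique assignment: nearest/second-nearest by squared Euclidean
# distance, ratio test on squared distances, then keep only the closest
# query per claimed reference. Tie-breaks: lowest reference index for equal
# distances, lowest query index for equal claims.
brute_force_direction <- function(Q, R, ratio = 0.6) {
  empty <- data.frame(query_idx = integer(0), ref_idx = integer(0),
                      d1_sq = numeric(0))
  if (nrow(Q) == 0L || nrow(R) < 2L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(Q))) {
    d <- vapply(seq_len(nrow(R)), function(j) sum((Q[i, ] - R[j, ])^2), 0)
    ord <- order(d)
    d1 <- d[ord[1L]]; d2 <- d[ord[2L]]
    if (d2 > 0 && d1 / d2 < ratio)
      rows[[length(rows) + 1L]] <- data.frame(query_idx = i,
                                              ref_idx = ord[1L], d1_sq = d1)
  }
  if (length(rows) == 0L) return(empty)
  p <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(p, p$ref_idx), function(g) {
    g[order(g$d1_sq, g$query_idx)[1L], ]
  }))
  out <- out[order(out$query_idx), ]
  rownames(out) <- NULL
  out
}

# Random feature set with distinct descriptors and keypoints in general
# position (no three collinear with probability 1).
random_feature_set <- function(n, d = 64L, seed = 1L) {
  set.seed(seed)
  kp <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100),
                   scale = rep(2, n), orientation = rep(0, n),
                   response = runif(n))
  feature_set(kp, matrix(rnorm(n * d), n, d))
}

# Minimal database wrapper around hand-made entries (identity metadata
# only; no image processing involved).
toy_database <- function(feature_sets, identity_ids,
                         sex = NULL, birth = NULL, study = NULL) {
  entries <- lapply(seq_along(feature_sets), function(i)
    list(entry_id = sprintf("e%02d", i),
         identity_id = identity_ids[i],
         exam_id = sprintf("x%02d", i),
         slice_index = i - 1L,
         feature_set = feature_sets[[i]],
         study_date = if (is.null(study)) "20150101" else study[i],
         birth_date = if (is.null(birth)) NA_character_ else birth[i],
         sex = if (is.null(sex)) "unknown" else sex[i]))
  sinusmatch:::new_cvdatabase(entries, "toy-fingerprint")
}
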