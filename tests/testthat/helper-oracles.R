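# Shared fixtures and independent oracles. Oracles are deliberately naive
# re-derivations (enumeration, flood fill, textbook formulas) kept free of
# the package code paths they check.

.mesh_cache <- new.env(parent = emptyenv())

test_mesh <- function(order, hemisphere = "left") {
  key <- sprintf("o%d_%s", order, hemisphere)
  if (is.null(.mesh_cache[[key]]))
    .mesh_cache[[key]] <- build_icosphere(order, hemisphere)
  .mesh_cache[[key]]
}

# Undirected edge list straight from the face table (independent of the
# package's adjacency code).
oracle_edges <- function(faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(as.data.frame(e))
}

# Flood-fill connected components of a masked vertex set.
oracle_components <- function(faces, mask) {
  n <- length(mask)
  ed <- oracle_edges(faces)
  keep <- mask[ed[, 1]] & mask[ed[, 2]]
  ed <- ed[keep, , drop = FALSE]
  label <- ifelse(mask, seq_len(n), 0L)
  repeat {
    new_label <- label
    if (nrow(ed)) {
      m <- pmin(label[ed[, 1]], label[ed[, 2]])
      for (r in seq_len(nrow(ed))) {
        new_label[ed[r, 1]] <- min(new_label[ed[r, 1]], m[r])
        new_label[ed[r, 2]] <- min(new_label[ed[r, 2]], m[r])
      }
    }
    if (identical(new_label, label)) break
    label <- new_label
  }
  unname(lapply(split(which(mask), label[mask]), sort))
}

# Concordant-pair AUC: P(score_pos "beats" score_neg) + half ties, with the
# lower-is-positive orientation applied by negation.
oracle_auc <- function(scores, labels, direction = "lower") {
  s <- if (direction == "lower") -scores else scores
  pos <- s[as.logical(labels)]
  neg <- s[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Textbook Welch t.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Hanley-McNeil standard error of an empirical AUC.
auc_se <- function(a, n1, n2) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n2 - 1) * (q2 - a^2)) /
         (n1 * n2))
}

# Minimal two-group cohort for vertex-model tests: thickness matrix columns
# follow the subject table.
make_mini_cohort <- function(thick_left, stage, age = NULL, sex = NULL,
                             thick_right = NULL) {
  n <- length(stage)
  subj <- data.frame(
    id = sprintf("T%03d", seq_len(n)),
    stage = factor(stage, levels = c("CS-", "CS+", "IMP+", "excluded")),
    age = age %||% rep(40, n),
    sex = sex %||% rep(c("male", "female"), length.out = n),
    apoe_e4 = rep(FALSE, n),
    tracer = rep("PiB", n),
    centiloid = rep(0, n),
    icv = rep(1.2e6, n))
  thickness <- list(left = thick_left)
  if (!is.null(thick_right)) thickness$right <- thick_right
  structure(list(subjects = subj, thickness = thickness,
                 meshes = NULL, volumes = NULL, truth = NULL, config = NULL),
            class = "ds_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built signature mask (bypasses derivation) for scoring/selection tests.
manual_mask <- function(masks, comparison = c("CS-", "IMP+"), vertex_p = 0.01,
                        area = NA_real_) {
  structure(list(masks = masks, comparison = comparison, vertex_p = vertex_p,
                 cluster_p = 0.001,
                 area_mm2 = area, clusters = NULL, n_perm = 0L),
            class = "signature_mask")
}
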