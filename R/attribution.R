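# Compensating-joint identification. For DoF j the weight-feature product
#   psi_j = w_{j,jerk} phi_{j,jerk} + w_{j,pow} phi_{j,pow}
#         + w_{j,eff}  phi_{j,eff}  + w_{j,tr}  phi_{j,tr}
# partitions the decision value: sum_j psi_j + b = w . phi + b. When a
# frame is classified as Compensation (decision < 0), the DoF with the
# most negative psi contributes the most to that call; positive psi marks
# DoFs used the way typical movements use them. The intercept carries no
# per-DoF share and is reported separately.

#' Per-DoF weight-feature attribution
#'
#' @param model a [fit_compensation_model()] fit.
#' @param phi one feature vector (raw by default; the model's scaler is
#'   applied) in the model's feature order.
#' @param normalized set `TRUE` if `phi` is already normalized.
#' @return object of class `"joint_attribution"`: list with `psi` (named
#'   per-DoF products), `ranking` (DoF names ascending by psi, most
#'   negative first; ties broken by canonical DoF order), `decision`,
#'   `intercept`, `label`.
#' @export
attribute_joints <- function(model, phi, normalized = FALSE) {
  if (!is.null(dim(phi))) {
    if (nrow(phi) != 1L) stop("phi must be a single feature vector")
    phi <- drop(as.matrix(phi))
  }
  if (length(phi) != length(model$w))
    stop(sprintf("feature count mismatch: model has %d, phi has %d",
                 length(model$w), length(phi)))
  if (!normalized) phi <- transform_minmax(model$scaler, phi)
  contrib <- model$w * phi
  dofs <- unique(sub("__.*$", "", names(model$w)))
  psi <- rowSums(matrix(contrib, nrow = length(dofs), byrow = TRUE))
  names(psi) <- dofs
  # order() is stable, so equal psi fall back to canonical DoF order
  ranking <- dofs[order(psi)]
  d <- sum(contrib) + model$b
  structure(list(psi = psi, ranking = ranking, decision = d,
                 intercept = model$b,
                 label = if (d < 0) "compensatory" else "healthy"),
            class = "joint_attribution")
}

#' @export
print.joint_attribution <- function(x, ...) {
  cat(sprintf("Joint attribution: decision %.4f => %s (intercept %.4f)\n",
              x$decision, x$label, x$intercept))
  df <- data.frame(dof = x$ranking, psi = round(x$psi[x$ranking], 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.joint_attribution <- function(x, ...) {
  psi <- x$psi[rev(x$ranking)]
  op <- par(mar = c(4, 9, 2, 1)); on.exit(par(op))
  barplot(psi, horiz = TRUE, las = 1,
          col = ifelse(psi < 0, "firebrick", "steelblue"),
          xlab = "weight-feature product psi",
          main = sprintf("Per-DoF attribution (%s)", x$label), ...)
  abline(v = 0)
  invisible(x)
}

#' Per-frame attribution trace over a feature series
#'
#' @param model a `"comp_model"`.
#' @param features matrix of per-frame feature vectors (raw).
#' @return matrix of psi values, rows = frames, columns = DoFs.
#' @export
attribution_trace <- function(model, features) {
  X <- transform_minmax(model$scaler, as.matrix(features))
  contrib <- sweep(X, 2, model$w, `*`)
  dofs <- unique(sub("__.*$", "", names(model$w)))
  out <- sapply(seq_along(dofs), function(j)
    rowSums(contrib[, (j - 1L) * 4L + 1:4, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  colnames(out) <- dofs
  out
}
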