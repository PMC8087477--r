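# Registration quality metrics: per-ROI Dice overlap and fold counts of the
# composed deformation.

#' Dice overlap between two label volumes
#'
#' Per-ROI Dice `2|A n B| / (|A| + |B|)` for every nonzero label id present
#' in either volume; background (label 0) is excluded. An ROI present in
#' only one volume scores 0 and is flagged (dropping it would silently
#' inflate the mean). The mean is the unweighted average over the union of
#' nonzero ROI ids.
#'
#' @param labels_a,labels_b integer-valued label volumes of identical shape.
#' @return Object of class `dice_report`: `per_roi` (data.frame with columns
#'   `roi`, `dice`, `in_both`) and `mean`.
#' @export
dice_overlap <- function(labels_a, labels_b) {
  check_volume(labels_a, "labels_a")
  check_volume(labels_b, "labels_b")
  check_same_shape(labels_a, labels_b, "label volumes")
  if (max(abs(labels_a - round(labels_a))) > 0 ||
      max(abs(labels_b - round(labels_b))) > 0) {
    stop("label volumes must be integer-valued")
  }
  ids <- sort(union(unique(as.vector(labels_a)), unique(as.vector(labels_b))))
  ids <- ids[ids != 0]
  if (length(ids) == 0) stop("no nonzero ROI labels present")
  per <- vapply(ids, function(i) {
    na <- sum(labels_a == i)
    nb <- sum(labels_b == i)
    c(dice = 2 * sum(labels_a == i & labels_b == i) / (na + nb),
      in_both = as.numeric(na > 0 && nb > 0))
  }, c(dice = 0, in_both = 0))
  structure(
    list(per_roi = data.frame(roi = ids, dice = per["dice", ],
                              in_both = per["in_both", ] > 0),
         mean = mean(per["dice", ])),
    class = "dice_report"
  )
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("Dice overlap over %d ROIs: mean %.4f\n", nrow(x$per_roi), x$mean))
  flagged <- x$per_roi$roi[!x$per_roi$in_both]
  if (length(flagged)) {
    cat("  ROIs present in only one volume:", paste(flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate a registration result against ROI label maps
#'
#' Resamples the subject labels onto the template grid with the composed
#' subject-to-template deformation (nearest neighbour, so no labels are
#' invented), scores the Dice overlap against the template labels, and
#' audits the smoothness of that composed field (interior fold count and
#' Jacobian-determinant extrema). The halfway field's own diagnostics are
#' reported alongside.
#'
#' @param result a [register_pair()] result.
#' @param labels_subject,labels_template integer label volumes on the image
#'   grid.
#' @return list with `dice` (a `dice_report`), `diagnostics`
#'   (`field_diagnostics` of the composed subject-to-template field) and
#'   `diagnostics_halfway`.
#' @export
evaluate_registration <- function(result, labels_subject, labels_template) {
  stopifnot(inherits(result, "registration_result"))
  check_same_shape(labels_subject, labels_template, "label volumes")
  check_same_shape(labels_subject, array(0, spatial_shape(result$backward)),
                   "labels and field grid")
  warped <- warp_labels(labels_subject, result$backward)
  list(
    dice = dice_overlap(warped, labels_template),
    diagnostics = field_diagnostics(result$backward),
    diagnostics_halfway = result$diagnostics_halfway
  )
}
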