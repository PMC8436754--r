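#' Read / write SEEG contact tables
#'
#' Contacts are exchanged as TSV with columns `contact_id`, `x_mm`,
#' `y_mm`, `z_mm` (world coordinates) and 0/1 role flags `onset`,
#' `propagation`, `interictal`. A contact with all flags 0 was sampled
#' but silent.
#'
#' @param path TSV file path.
#' @return data.frame of contacts.
#' @export
read_contacts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contact_id", "x_mm", "y_mm", "z_mm", "onset",
            "propagation", "interictal")
  missing <- setdiff(need, colnames(tab))
  if (length(missing))
    stop("contact table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab
}

#' @rdname read_contacts
#' @param contacts data.frame of contacts.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# world-mm coordinates of all above-threshold voxel centres
abnormal_voxel_coords <- function(map) {
  idx <- which(map$binary, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), ncol = 3L))
  voxel_to_world(idx, map$probabilities$affine)
}

min_dist_to_coords <- function(pos, coords) {
  if (nrow(coords) == 0L) return(Inf)
  sqrt(min(colSums((t(coords) - pos)^2)))
}

#' Overlap between one SEEG contact sphere and the abnormality mask
#'
#' A sphere of `diameter_mm` is centred at the contact position; the
#' contact overlaps the map when some above-threshold voxel centre lies
#' within `diameter_mm / 2` of it (inclusive). The minimum Euclidean
#' distance from the contact to the nearest abnormal voxel centre is also
#' returned (`Inf` for an empty mask). A contact outside the lattice
#' bounding box is still evaluated, with a warning.
#'
#' @param contact numeric xyz (world mm) or a one-row contact data.frame.
#' @param map an [abnormality_map].
#' @param diameter_mm sphere diameter in mm (default 10).
#' @return list with `overlaps` (logical) and `min_distance_mm`.
#' @export
contact_sphere_overlap <- function(contact, map, diameter_mm = 10.0) {
  if (diameter_mm <= 0)
    stop("diameter_mm must be positive", call. = FALSE)
  if (is.data.frame(contact))
    contact <- as.numeric(contact[1, c("x_mm", "y_mm", "z_mm")])
  contact <- as.numeric(contact)
  dims <- dim(map$binary)
  corners <- as.matrix(expand.grid(c(1, dims[1]), c(1, dims[2]),
                                   c(1, dims[3])))
  world <- voxel_to_world(corners, map$probabilities$affine)
  if (any(contact < apply(world, 2, min) - 1e-6) ||
      any(contact > apply(world, 2, max) + 1e-6))
    warning("contact lies outside the image bounding box")
  d <- min_dist_to_coords(contact, abnormal_voxel_coords(map))
  list(overlaps = is.finite(d) && d <= diameter_mm / 2,
       min_distance_mm = d)
}

#' Structured SEEG-vs-map concordance assessment
#'
#' Codifies the structured comparison between an abnormality map and SEEG
#' findings as deterministic rules (the clinical counterpart is a
#' consensus visual reading; this report is algorithmic). Each contact is
#' a 10 mm diameter sphere; "areas" are the face-connected components of
#' the binary mask. Five determinations are made: whether the seizure
#' onset zone, early propagation, and interictal discharges fall within
#' abnormal areas (any contact with that role overlapping the mask);
#' whether some abnormal area is sampled by no contact sphere; and
#' whether some abnormal area is touched only by role-free (silent)
#' contacts. The subject is assigned Group A (SoZ detected: an onset
#' contact overlaps), Group B (onset contacts exist but none overlaps) or
#' Group C (no onset contact: SEEG inconclusive).
#'
#' @param contacts contact data.frame (see [read_contacts]), nonempty.
#' @param map an [abnormality_map].
#' @param diameter_mm sphere diameter in mm.
#' @return An object of class `concordance_report`: the five logical
#'   determinations, `group`, per-contact `distances_mm`, and the
#'   per-component classification (`component_status`).
#' @export
assess_concordance <- function(contacts, map, diameter_mm = 10.0) {
  if (nrow(contacts) == 0L)
    stop("contact table is empty", call. = FALSE)
  radius <- diameter_mm / 2
  coords <- abnormal_voxel_coords(map)
  pos <- as.matrix(contacts[, c("x_mm", "y_mm", "z_mm")])
  dist_mask <- apply(pos, 1L, min_dist_to_coords, coords = coords)
  overlaps <- is.finite(dist_mask) & dist_mask <= radius
  has_role <- contacts$onset + contacts$propagation +
    contacts$interictal > 0

  comp <- label_components(map$binary)
  n_comp <- attr(comp, "n_components")
  comp_status <- character(0)
  if (n_comp > 0) {
    comp_status <- vapply(seq_len(n_comp), function(ci) {
      cidx <- which(comp == ci, arr.ind = TRUE)
      cw <- voxel_to_world(cidx, map$probabilities$affine)
      touching <- vapply(seq_len(nrow(pos)), function(ct)
        min_dist_to_coords(pos[ct, ], cw) <= radius, logical(1))
      if (!any(touching)) "unsampled"
      else if (any(touching & has_role)) "role_overlapped"
      else "sampled_silent"
    }, character(1))
  }

  onset_present <- any(contacts$onset > 0)
  soz <- any(overlaps & contacts$onset > 0)
  report <- list(
    soz_within_abnormal = soz,
    propagation_within_abnormal = any(overlaps &
                                        contacts$propagation > 0),
    ied_within_abnormal = any(overlaps & contacts$interictal > 0),
    abnormal_unsampled = any(comp_status == "unsampled"),
    abnormal_sampled_silent = any(comp_status == "sampled_silent"),
    group = if (!onset_present) "C" else if (soz) "A" else "B",
    distances_mm = setNames(dist_mask, contacts$contact_id),
    component_status = comp_status,
    diameter_mm = diameter_mm)
  structure(report, class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> group ", x$group, "\n",
      "  SoZ within abnormal:          ", x$soz_within_abnormal, "\n",
      "  propagation within abnormal:  ",
      x$propagation_within_abnormal, "\n",
      "  IED within abnormal:          ", x$ied_within_abnormal, "\n",
      "  abnormal areas unsampled:     ", x$abnormal_unsampled, "\n",
      "  abnormal areas sampled+silent:", x$abnormal_sampled_silent,
      "\n", sep = "")
  invisible(x)
}
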