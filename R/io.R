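# JSON serialization of kernel sets and energy records, for moving
# intermediate results between pipeline stages or external tools.

#' Write a kernel set to JSON
#'
#' Documented layout: an array of objects with `label`, `origin`,
#' `formal_charge`, `multiplicity`, `atoms` and `caps` (atom tables as
#' arrays of records).
#'
#' @param kernels list of [kernel()] objects
#' @param path output file
#' @return `path`, invisibly
#' @export
write_kernels_json <- function(kernels, path) {
  payload <- lapply(unname(kernels), function(k)
    list(label = k$label, origin = k$origin,
         formal_charge = k$formal_charge, multiplicity = k$multiplicity,
         atoms = k$atoms, caps = k$caps))
  jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Read a kernel set from JSON
#'
#' @param path file written by [write_kernels_json()]
#' @return named list of [kernel()] objects
#' @export
read_kernels_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  kerns <- lapply(seq_len(nrow(payload)), function(i) {
    caps <- payload$caps[[i]]
    if (is.null(caps) || length(caps) == 0 || nrow(caps) == 0) caps <- NULL
    kernel(payload$label[[i]], payload$atoms[[i]],
           origin = payload$origin[[i]], caps = caps,
           formal_charge = payload$formal_charge[[i]],
           multiplicity = payload$multiplicity[[i]])
  })
  names(kerns) <- payload$label
  kerns
}

#' Write KEM interaction-energy results to JSON
#'
#' Carries the per-residue pairwise IE table (raw, CP, averaged) and the
#' total averaged protein-ligand IE.
#'
#' @param result a [protein_ligand_ie()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ie_json <- function(result, path) {
  jsonlite::write_json(
    list(ie_total = result$ie_total, n_kernels = result$n_kernels,
         complete = result$complete, missing_pairs = result$missing_pairs,
         ie_pairwise = result$ie_pairwise),
    path, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(path)
}
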