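#' The 19-channel 10-20 montage
#'
#' Electrode labels of the standard 19-channel International 10-20 montage
#' used throughout the pipeline, in canonical (anterior-to-posterior) order.
#'
#' @return Character vector of 19 electrode labels.
#' @export
montage_electrodes <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Electrode adjacency graph for the 19-channel 10-20 montage
#'
#' Spatial neighbourhood of scalp electrodes used to group supra-threshold
#' electrodes into connected clusters. Neighbours are the nearest electrodes
#' along the anterior-posterior and left-right axes of the 10-20 layout
#' (e.g. C3 borders F3, Cz, P3 and T3). The table ships as a plain-text edge
#' list in `inst/extdata/montage_1020_adjacency.tsv`.
#'
#' @param path Optional path to an alternative edge list (two tab-separated
#'   columns of electrode labels, one edge per row; a header row is allowed).
#' @return A symmetric 19 x 19 logical adjacency matrix with electrode
#'   dimnames and a zero diagonal.
#' @export
montage_adjacency <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "montage_1020_adjacency.tsv",
                        package = "tactileEEG", mustWork = TRUE)
  }
  edges <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  electrodes <- montage_electrodes()
  bad <- setdiff(unique(c(edges[[1]], edges[[2]])), electrodes)
  if (length(bad) > 0) {
    stop("adjacency edge list names unknown electrode(s): ",
         paste(bad, collapse = ", "))
  }
  adj <- matrix(FALSE, length(electrodes), length(electrodes),
                dimnames = list(electrodes, electrodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (a == b) stop("self-loop in adjacency edge list: ", a)
    adj[a, b] <- TRUE
    adj[b, a] <- TRUE
  }
  adj
}

#' Connected components of an electrode set
#'
#' Flood-fill decomposition of a subset of electrodes into connected
#' components under the montage adjacency. Written as a tight loop over the
#' adjacency matrix because it sits inside the permutation resampling loop.
#'
#' @param members Integer or logical index of electrodes in the set.
#' @param adjacency Adjacency matrix from [montage_adjacency()].
#' @return A list of integer vectors, one per component, each sorted;
#'   components are ordered by their smallest member.
#' @keywords internal
connected_components <- function(members, adjacency) {
  if (is.logical(members)) members <- which(members)
  if (length(members) == 0) return(list())
  in_set <- logical(nrow(adjacency))
  in_set[members] <- TRUE
  seen <- logical(nrow(adjacency))
  comps <- list()
  for (start in members) {
    if (seen[start]) next
    stack <- start
    comp <- integer(0)
    seen[start] <- TRUE
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      nb <- which(adjacency[v, ] & in_set & !seen)
      if (length(nb) > 0) {
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
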