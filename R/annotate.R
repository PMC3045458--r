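#' Functional categories recognized in annotation maps
#' @export
annotation_categories <- function() {
  c("Transcription/Translation", "Signaling", "Protein Processing",
    "Energy Metabolism", "Immune/Inflammatory", "Small Molecule Metabolism",
    "Cell Cycle Control", "Transport", "Miscellaneous", "EST")
}

#' Probe-set to gene rollup
#'
#' Collapses a survivor probe-set list to distinct genes through an
#' annotation map, counting unmapped probe sets (gene symbol
#' \code{"UNMAPPED"}, category EST), duplicate-gene instances (extra probe
#' sets beyond the first for the same symbol), and probe sets per
#' functional category.
#'
#' @param survivors Character vector of probe-set ids.
#' @param map Annotation data frame with columns \code{probe_set_id},
#'   \code{gene_symbol}, \code{category}; one row per probe set; unmapped
#'   probe sets carry symbol \code{"UNMAPPED"}.
#' @return List of class \code{"rollup_report"}: \code{n_probe_sets},
#'   \code{n_unmapped}, \code{n_mapped}, \code{n_genes},
#'   \code{n_duplicate_instances}, and \code{category_counts} (named
#'   integer vector summing to \code{n_probe_sets}).
#' @export
rollup <- function(survivors, map) {
  need <- c("probe_set_id", "gene_symbol", "category")
  if (!all(need %in% names(map)))
    stop("annotation map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(map$probe_set_id))
    stop("annotation map has duplicate probe_set_id rows")
  survivors <- unique(as.character(survivors))
  hit <- match(survivors, map$probe_set_id)
  if (anyNA(hit))
    stop("unannotated probe set(s): ",
         paste(survivors[is.na(hit)], collapse = ", "))
  sym <- map$gene_symbol[hit]
  cat_ <- map$category[hit]
  unmapped <- sym == "UNMAPPED"
  n_mapped <- sum(!unmapped)
  n_genes <- length(unique(sym[!unmapped]))
  counts <- table(factor(cat_, levels = union(annotation_categories(),
                                              unique(cat_))))
  structure(list(n_probe_sets = length(survivors),
                 n_unmapped = sum(unmapped),
                 n_mapped = n_mapped,
                 n_genes = n_genes,
                 n_duplicate_instances = n_mapped - n_genes,
                 category_counts = c(counts)),
            class = "rollup_report")
}

#' @export
print.rollup_report <- function(x, ...) {
  cat(sprintf(paste0("Rollup: %d probe sets = %d unmapped + %d mapped; ",
                     "%d distinct genes (%d duplicate instances)\n"),
              x$n_probe_sets, x$n_unmapped, x$n_mapped,
              x$n_genes, x$n_duplicate_instances))
  nz <- x$category_counts[x$category_counts > 0]
  if (length(nz))
    cat(paste0("  ", names(nz), ": ", nz, collapse = "\n"), "\n")
  invisible(x)
}

#' Cross-tissue overlap of probe-set lists
#'
#' Sizes of two survivor lists (e.g. adipose and liver) and of their
#' intersection.
#'
#' @param set_a,set_b Character vectors of probe-set ids.
#' @return Named list \code{n_a}, \code{n_b}, \code{n_shared}.
#' @export
overlap_sets <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  list(n_a = length(a), n_b = length(b),
       n_shared = length(intersect(a, b)))
}
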