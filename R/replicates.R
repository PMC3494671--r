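#' Declare replicate pairs of single individuals
#'
#' Replicated AFLP profiles — a second, independently generated profile of
#' the same DNA source — are the basis of all reliability scoring. A
#' replicate set pairs two sample IDs per replicated individual; third or
#' later replicates of the same individual are not scored and are kept
#' only as control samples (`extras`).
#'
#' @param pairs two-column matrix or data.frame of sample IDs
#'   (first replicate, second replicate), one row per replicated
#'   individual.
#' @param extras optional character vector of sample IDs of further
#'   replicates excluded from scoring.
#' @param matrix optional `aflp_matrix`; when given, all referenced IDs
#'   are checked against its samples.
#' @return An object of class `replicate_set` with elements `pairs`
#'   (data.frame with columns `a`, `b`, `pair_id`) and `extras`.
#' @examples
#' replicate_set(rbind(c("ind1", "ind1_rep"), c("ind2", "ind2_rep")))
#' @export
replicate_set <- function(pairs, extras = character(), matrix = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2 || nrow(pairs) == 0)
    stop("`pairs` must have one row per replicate pair and two columns")
  pairs <- data.frame(a = as.character(pairs[[1]]),
                      b = as.character(pairs[[2]]),
                      stringsAsFactors = FALSE)
  if (any(pairs$a == pairs$b))
    stop("a sample cannot be paired with itself: ",
         paste(pairs$a[pairs$a == pairs$b], collapse = ", "))
  ids <- c(pairs$a, pairs$b)
  if (anyDuplicated(ids))
    stop("sample ID(s) occur in more than one pair: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pairs$pair_id <- paste(pairs$a, pairs$b, sep = "|")
  obj <- structure(list(pairs = pairs,
                        extras = as.character(extras)),
                   class = "replicate_set")
  if (!is.null(matrix)) check_replicates(obj, matrix)
  obj
}

check_replicates <- function(reps, matrix) {
  ids <- c(reps$pairs$a, reps$pairs$b, reps$extras)
  missing <- setdiff(ids, sample_ids(matrix))
  if (length(missing))
    stop("replicate sample(s) not found in matrix: ",
         paste(missing, collapse = ", "))
  invisible(reps)
}

#' Read a replicate declaration file
#'
#' Plain two-column delimited text (no header): first and second replicate
#' sample ID per row.
#'
#' @param path file path.
#' @param sep field delimiter (default: any whitespace).
#' @return A `replicate_set`.
#' @export
read_replicates <- function(path, sep = "") {
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  replicate_set(tab[, 1:2])
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("Replicate set: %d pair(s)", nrow(x$pairs)))
  if (length(x$extras))
    cat(sprintf(", %d extra control profile(s)", length(x$extras)))
  cat("\n")
  invisible(x)
}
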