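#' Construct a pedigree object
#'
#' A pedigree is an ordered set of (animal, sire, dam) triples in which every
#' parent appears before any of its offspring.  Unknown parents are coded
#' `NA`, `0` or `""` on input and stored as index 0 internally; they are
#' treated as unrelated, non-inbred founders.
#'
#' @param id character or integer vector of unique animal identifiers, in
#'   topological (parents-first) order.
#' @param sire,dam parent identifiers aligned with `id`; `NA`/`0`/`""` for
#'   unknown.
#' @param sex optional per-animal sex code (`"M"`/`"F"`), kept as metadata.
#' @param generation optional integer generation number, kept as metadata.
#'
#' @return An object of class `pedigree`: a list with elements `id`
#'   (character), `sire` and `dam` (integer indices into `id`, 0 = unknown),
#'   `n`, and optional `sex`/`generation` metadata.
#' @export
pedigree <- function(id, sire, dam, sex = NULL, generation = NULL) {
  id <- as.character(id)
  n <- length(id)
  if (n == 0L) stop("pedigree must contain at least one animal")
  if (anyDuplicated(id)) {
    stop("duplicated animal ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sire_i <- .parent_index(sire, id)
  dam_i  <- .parent_index(dam, id)
  bad <- which(sire_i == seq_len(n) | dam_i == seq_len(n))
  if (length(bad)) stop("animal is its own parent: ", id[bad[1L]])
  late <- which(sire_i > seq_len(n) | dam_i > seq_len(n))
  if (length(late)) {
    stop("pedigree not topologically ordered: parents of '", id[late[1L]],
         "' appear after it")
  }
  ped <- list(id = id, sire = sire_i, dam = dam_i, n = n)
  if (!is.null(sex)) ped$sex <- as.character(sex)
  if (!is.null(generation)) ped$generation <- as.integer(generation)
  class(ped) <- "pedigree"
  ped
}

.parent_index <- function(par, id) {
  par <- as.character(par)
  par[is.na(par) | par == "0" | par == ""] <- NA_character_
  idx <- match(par, id)
  missing <- !is.na(par) & is.na(idx)
  if (any(missing)) {
    stop("parent id not in pedigree: ",
         paste(unique(par[missing]), collapse = ", "))
  }
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(x$sire == 0L & x$dam == 0L)
  cat("pedigree: ", x$n, " animals (", nf, " founders)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(
    animal = x$id,
    sire = ifelse(x$sire == 0L, "0", x$id[pmax(x$sire, 1L)]),
    dam  = ifelse(x$dam == 0L, "0", x$id[pmax(x$dam, 1L)]),
    stringsAsFactors = FALSE
  )
}

#' Look up pedigree indices for animal ids
#'
#' @param ped a [pedigree()].
#' @param ids animal identifiers.
#' @return integer positions in pedigree order.
#' @export
ped_index <- function(ped, ids) {
  idx <- match(as.character(ids), ped$id)
  if (anyNA(idx)) {
    stop("ids not in pedigree: ",
         paste(unique(ids[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Read a pedigree from a CSV file
#'
#' Expects columns `animal,sire,dam` (header required); `0`, `NA` or empty
#' fields denote unknown parents.  Extra columns are ignored.
#'
#' @param path file path.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns animal,sire,dam")
  }
  pedigree(df$animal, df$sire, df$dam)
}

#' Write a pedigree to CSV (animal,sire,dam; 0 = unknown parent)
#'
#' @param ped a [pedigree()].
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
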