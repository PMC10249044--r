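#' Build the social pedigree from nest records
#'
#' Field observation links every ringed nestling to the adults attending
#' its natal nest (the *social* mother and father). Those links are what
#' the genomic relatedness matrix is compared against: a discrepancy
#' between the two is the signal for extra-pair paternity or brood
#' parasitism.
#'
#' @param nests nest-record tibble with columns `nest_id`, `year`,
#'   `mother_id`, `father_id` (`NA` when the adult was not identified).
#' @param nestlings tibble with columns `id` and `nest_id` linking each
#'   ringed nestling to its natal nest.
#' @return A `social_pedigree` tibble with columns `id`, `mother`,
#'   `father`, `year`, `natal_nest` (adults appear as founders with
#'   unknown parents). A `validation` attribute reports duplicate-entry
#'   merges.
#' @export
build_pedigree <- function(nests, nestlings) {
  nests <- as_tibble(nests)
  nestlings <- as_tibble(nestlings)
  off <- nestlings %>%
    left_join(nests %>% select("nest_id", "mother_id", "father_id", "year"),
              by = "nest_id") %>%
    mutate(
      mother = .data$mother_id, father = .data$father_id,
      natal_nest = .data$nest_id
    ) %>%
    select("id", "mother", "father", "year", "natal_nest")
  if (anyDuplicated(off$id)) abort("nestling id appears in more than one nest")
  adults <- unique(na.omit(c(nests$mother_id, nests$father_id)))
  adults <- setdiff(adults, off$id)  # cross-year recruits keep their links
  ped <- bind_rows(
    tibble(id = adults, mother = NA_character_, father = NA_character_,
           year = NA_integer_, natal_nest = NA_character_),
    off
  )
  validate_pedigree(ped)
  structure(ped, class = c("social_pedigree", class(ped)))
}

#' Coerce a data frame to a social pedigree
#'
#' @param x data frame with at least `id`, `mother`, `father` columns.
#' @return A `social_pedigree` tibble.
#' @export
as_pedigree <- function(x) {
  x <- as_tibble(x)
  need <- c("id", "mother", "father")
  if (!all(need %in% names(x))) abort("pedigree needs id, mother, father columns")
  if (!"year" %in% names(x)) x$year <- NA_integer_
  if (!"natal_nest" %in% names(x)) x$natal_nest <- NA_character_
  validate_pedigree(x)
  structure(x, class = c("social_pedigree", class(x)))
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) abort("duplicate ids in pedigree")
  # cycle check via iterative ancestor sweep
  parents <- rbind(
    cbind(ped$id, ped$mother),
    cbind(ped$id, ped$father)
  )
  parents <- parents[!is.na(parents[, 2]), , drop = FALSE]
  unknown <- setdiff(parents[, 2], ped$id)
  # parents never ringed as nestlings are implicit founders; fine
  if (nrow(parents)) {
    anc <- split(parents[, 2], parents[, 1])
    for (id in names(anc)) {
      seen <- character()
      frontier <- anc[[id]]
      while (length(frontier)) {
        if (id %in% frontier)
          abort(sprintf("pedigree cycle: %s is its own ancestor", id))
        seen <- union(seen, frontier)
        frontier <- unlist(anc[intersect(frontier, names(anc))], use.names = FALSE)
        frontier <- setdiff(frontier, seen)
      }
    }
  }
  invisible(ped)
}

# topological order: parents before offspring
.ped_order <- function(ped) {
  ids <- ped$id
  mo <- match(ped$mother, ids)
  fa <- match(ped$father, ids)
  placed <- rep(FALSE, length(ids))
  ord <- integer(0)
  while (length(ord) < length(ids)) {
    ready <- !placed &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)]) &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)])
    if (!any(ready)) abort("pedigree is not acyclic")
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  ord
}

# full additive relationship matrix by the tabular (recursive) method
.a_matrix <- function(ped) {
  ord <- .ped_order(ped)
  ped <- ped[ord, ]
  n <- nrow(ped)
  ids <- ped$id
  mo <- match(ped$mother, ids)
  fa <- match(ped$father, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- fa[i]; d <- mo[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      as <- if (!is.na(s)) A[j, s] else 0
      ad <- if (!is.na(d)) A[j, d] else 0
      A[j, i] <- A[i, j] <- (as + ad) / 2
    }
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
  }
  A
}

#' Expected additive relatedness from the social pedigree
#'
#' Tabular (recursive) method: `a_ii = 1 + a(sire, dam)/2` and
#' `a_ij = (a(i, sire_j) + a(i, dam_j)) / 2`, with unknown parents
#' contributing 0. Handles inbreeding without special-casing.
#'
#' @param ped a `social_pedigree` (see [build_pedigree()]).
#' @param i,j individual ids.
#' @return The additive relationship value (0.5 for parent-offspring or
#'   full siblings, 0.25 for half siblings, ...).
#' @export
expected_relatedness <- function(ped, i, j) {
  if (!all(c(i, j) %in% ped$id))
    abort(sprintf("id not in pedigree: %s",
                  paste(setdiff(c(i, j), ped$id), collapse = ", ")))
  A <- .a_matrix(ped)
  A[i, j]
}

#' Social relatedness matrix aligned to a set of ids
#'
#' @param ped a `social_pedigree`.
#' @param ids individual ids in the order of the genomic relatedness
#'   matrix they will be compared to.
#' @return Symmetric matrix of expected additive relatedness among `ids`.
#' @export
social_relatedness_matrix <- function(ped, ids) {
  if (!all(ids %in% ped$id))
    abort(sprintf("ids not in pedigree: %s",
                  paste(head(setdiff(ids, ped$id), 5), collapse = ", ")))
  A <- .a_matrix(ped)
  A[ids, ids, drop = FALSE]
}

#' Read/write pedigree CSV
#'
#' Columns `id,mother,father,year,natal_nest`; unknown parents are empty
#' strings. Round-trips losslessly.
#'
#' @param ped pedigree tibble; `path` file path.
#' @name pedigree_io
#' @export
write_pedigree_csv <- function(ped, path) {
  out <- as.data.frame(ped)
  for (col in c("mother", "father", "natal_nest"))
    out[[col]][is.na(out[[col]])] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname pedigree_io
#' @param path file path.
#' @export
read_pedigree_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("mother", "father", "natal_nest"))
    x[[col]][x[[col]] == ""] <- NA_character_
  x$year <- suppressWarnings(as.integer(x$year))
  as_pedigree(as_tibble(x))
}
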