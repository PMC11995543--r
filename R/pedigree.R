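#' Read a 6-column PED pedigree file
#'
#' Standard PLINK-style PED layout: family id, individual id, sire id, dam id,
#' sex, phenotype; `0` marks an unknown parent.
#'
#' @param path Path to a whitespace-delimited PED file.
#' @return A `dnm_pedigree` data.frame (see [as_pedigree()]).
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) .stopf("pedigree file not found: %s", path)
  df <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) .stopf("malformed PED file %s: %s", path, conditionMessage(e)))
  if (ncol(df) < 6)
    .stopf("malformed PED file %s: expected 6 columns, found %d", path, ncol(df))
  names(df)[1:6] <- c("fam", "id", "sire", "dam", "sex", "phenotype")
  as_pedigree(df[, 1:6])
}

#' Validate a pedigree table
#'
#' Checks individual-id uniqueness and the absence of ancestry cycles
#' (no individual may be its own ancestor). Unknown parents (`"0"`, `""`,
#' `NA`) are normalised to `NA`.
#'
#' @param df data.frame with columns `fam`, `id`, `sire`, `dam`, `sex`,
#'   `phenotype` (character ids).
#' @return The validated `dnm_pedigree`.
#' @export
as_pedigree <- function(df) {
  needed <- c("fam", "id", "sire", "dam", "sex", "phenotype")
  miss <- setdiff(needed, names(df))
  if (length(miss)) .stopf("pedigree lacks column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("id", "sire", "dam")) df[[col]] <- as.character(df[[col]])
  df$sire[df$sire %in% c("0", "") | is.na(df$sire)] <- NA_character_
  df$dam[df$dam %in% c("0", "") | is.na(df$dam)] <- NA_character_
  if (anyDuplicated(df$id))
    .stopf("duplicated individual id(s): %s",
           paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  .check_no_cycles(df)
  rownames(df) <- NULL
  class(df) <- c("dnm_pedigree", "data.frame")
  df
}

## DFS over parent links; errors if any individual is its own ancestor.
.check_no_cycles <- function(df) {
  sire <- stats::setNames(df$sire, df$id)
  dam <- stats::setNames(df$dam, df$id)
  state <- stats::setNames(integer(nrow(df)), df$id)  # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (is.na(id) || !(id %in% names(state))) return(invisible())
    if (state[[id]] == 1L) .stopf("pedigree cycle: '%s' is its own ancestor", id)
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    visit(sire[[id]]); visit(dam[[id]])
    state[[id]] <<- 2L
  }
  for (id in df$id) visit(id)
  invisible(df)
}

#' Derive the trios declared by a pedigree
#'
#' A trio is any individual with both parents known; the offspring is the
#' proband in which de novo mutations are sought.
#'
#' @param ped A `dnm_pedigree`.
#' @return data.frame with columns `trio_id`, `proband`, `sire`, `dam`
#'   (trio id equals the proband id).
#' @export
trios <- function(ped) {
  keep <- !is.na(ped$sire) & !is.na(ped$dam)
  data.frame(trio_id = ped$id[keep], proband = ped$id[keep],
             sire = ped$sire[keep], dam = ped$dam[keep],
             stringsAsFactors = FALSE)
}

#' Half-sibs and offspring of a proband
#'
#' `half_sibs()` returns every other individual sharing at least one known
#' parent with the proband — half sibs proper and full sibs alike, since a
#' full sib can legitimately inherit the same parental-mosaic mutation.
#' `offspring_of()` returns individuals having the proband as sire or dam.
#' `derive_relatives()` bundles both; these relatives are exempt from the
#' cohort-uniqueness screen in [population_screen()].
#'
#' @param ped A `dnm_pedigree`.
#' @param proband Individual id present in the pedigree.
#' @return Character vector of ids (`derive_relatives()`: a list with elements
#'   `half_sibs` and `offspring`).
#' @export
half_sibs <- function(ped, proband) {
  i <- match(proband, ped$id)
  if (is.na(i)) .stopf("unknown proband id '%s'", proband)
  parents <- stats::na.omit(c(ped$sire[i], ped$dam[i]))
  if (!length(parents)) return(character(0))
  share <- (ped$sire %in% parents) | (ped$dam %in% parents)
  setdiff(ped$id[share], proband)
}

#' @rdname half_sibs
#' @export
offspring_of <- function(ped, proband) {
  if (!(proband %in% ped$id)) .stopf("unknown proband id '%s'", proband)
  ped$id[(!is.na(ped$sire) & ped$sire == proband) |
           (!is.na(ped$dam) & ped$dam == proband)]
}

#' @rdname half_sibs
#' @export
derive_relatives <- function(ped, proband) {
  list(half_sibs = half_sibs(ped, proband),
       offspring = offspring_of(ped, proband))
}

#' Generation depth of descendants below a proband
#'
#' Generation 1 is the proband itself; its offspring are generation 2, and so
#' on. Individuals reachable by several paths take the shortest.
#'
#' @param ped A `dnm_pedigree`.
#' @param proband Founder individual id.
#' @return Named integer vector of generations, covering the proband and all
#'   pedigree descendants.
#' @export
descendant_generations <- function(ped, proband) {
  if (!(proband %in% ped$id)) .stopf("unknown proband id '%s'", proband)
  gen <- stats::setNames(1L, proband)
  frontier <- proband
  while (length(frontier)) {
    nxt <- character(0)
    for (f in frontier) {
      for (k in offspring_of(ped, f)) {
        g <- gen[[f]] + 1L
        if (!(k %in% names(gen)) || g < gen[[k]]) {
          gen[k] <- g
          nxt <- c(nxt, k)
        }
      }
    }
    frontier <- unique(nxt)
  }
  gen
}

#' Write a pedigree as a 6-column PED file
#'
#' @param ped A `dnm_pedigree`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.table(out[, c("fam", "id", "sire", "dam", "sex", "phenotype")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
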