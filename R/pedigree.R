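#' Construct and validate a pedigree
#'
#' A pedigree is a tibble of family members with sex, affected status,
#' parent links and exactly one proband (the index affected individual).
#'
#' @param members A data frame with columns `id`, `sex` (`"MALE"`, `"FEMALE"`
#'   or `"UNKNOWN"`), `affected` (`"AFFECTED"`, `"UNAFFECTED"` or
#'   `"UNKNOWN"`), `father_id`, `mother_id` (`NA` when unknown) and logical
#'   `proband`.
#' @return A validated tibble of class `mm_pedigree`.
#' @export
pedigree <- function(members) {
  ped <- as_tibble(members)
  required <- c("id", "sex", "affected", "father_id", "mother_id", "proband")
  missing_cols <- setdiff(required, names(ped))
  if (length(missing_cols) > 0) {
    abort(paste0("Pedigree is missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "mm_pedigree_error")
  }
  ped <- mutate(ped,
    id = as.character(.data$id),
    sex = toupper(as.character(.data$sex)),
    affected = toupper(as.character(.data$affected)),
    father_id = as.character(.data$father_id),
    mother_id = as.character(.data$mother_id),
    proband = as.logical(.data$proband)
  )
  if (anyDuplicated(ped$id)) {
    abort("Pedigree member ids must be unique.", class = "mm_pedigree_error")
  }
  if (!all(ped$sex %in% c("MALE", "FEMALE", "UNKNOWN"))) {
    abort("sex must be MALE, FEMALE or UNKNOWN.", class = "mm_pedigree_error")
  }
  if (!all(ped$affected %in% c("AFFECTED", "UNAFFECTED", "UNKNOWN"))) {
    abort("affected must be AFFECTED, UNAFFECTED or UNKNOWN.", class = "mm_pedigree_error")
  }
  if (sum(ped$proband, na.rm = TRUE) != 1L) {
    abort("Pedigree must designate exactly one proband.", class = "mm_pedigree_error")
  }
  for (col in c("father_id", "mother_id")) {
    refs <- ped[[col]]
    known <- refs[!is.na(refs)]
    if (!all(known %in% ped$id)) {
      abort(paste0(col, " refers to id(s) absent from the pedigree: ",
                   paste(setdiff(known, ped$id), collapse = ", ")),
            class = "mm_pedigree_error")
    }
  }
  fathers <- ped$father_id[!is.na(ped$father_id)]
  if (any(ped$sex[match(fathers, ped$id)] == "FEMALE")) {
    abort("A father must not be FEMALE.", class = "mm_pedigree_error")
  }
  mothers <- ped$mother_id[!is.na(ped$mother_id)]
  if (any(ped$sex[match(mothers, ped$id)] == "MALE")) {
    abort("A mother must not be MALE.", class = "mm_pedigree_error")
  }
  # no individual is its own ancestor
  parent_of <- function(id) {
    row <- ped[ped$id == id, ]
    stats::na.omit(c(row$father_id, row$mother_id))
  }
  for (id in ped$id) {
    seen <- character()
    frontier <- parent_of(id)
    while (length(frontier) > 0) {
      if (id %in% frontier) {
        abort(paste0("Cyclic parentage involving '", id, "'."),
              class = "mm_pedigree_error")
      }
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parent_of))), seen)
    }
  }
  class(ped) <- c("mm_pedigree", class(ped))
  ped
}

#' Read a pedigree from a PED-dialect file
#'
#' Expects a tab- or whitespace-separated file with the six classic PED
#' columns (family, individual, father, mother, sex, phenotype) plus a
#' seventh proband-marker column (`1`/`yes`/`proband` marks the proband).
#' `0` in parent columns means unknown; sex is `1` = male, `2` = female;
#' phenotype is `1` = unaffected, `2` = affected, `0`/`-9` = unknown.
#'
#' @param path Path to the PED file.
#' @return An `mm_pedigree` tibble.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 7) {
    abort("PED file needs 7 columns: family, id, father, mother, sex, phenotype, proband.",
          class = "mm_pedigree_error")
  }
  names(raw)[1:7] <- c("family", "id", "father", "mother", "sex", "phen", "pro")
  pedigree(tibble(
    id = raw$id,
    sex = dplyr::case_match(raw$sex, "1" ~ "MALE", "2" ~ "FEMALE", .default = "UNKNOWN"),
    affected = dplyr::case_match(raw$phen, "1" ~ "UNAFFECTED", "2" ~ "AFFECTED",
                                 .default = "UNKNOWN"),
    father_id = ifelse(raw$father == "0", NA_character_, raw$father),
    mother_id = ifelse(raw$mother == "0", NA_character_, raw$mother),
    proband = tolower(raw$pro) %in% c("1", "yes", "proband", "true")
  ))
}

#' Write a pedigree to a PED-dialect file
#'
#' @param ped An `mm_pedigree`.
#' @param path Output path.
#' @param family Family identifier written in column 1.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, family = "FAM1") {
  lines <- vapply(seq_len(nrow(ped)), function(i) {
    r <- ped[i, ]
    paste(family, r$id,
          ifelse(is.na(r$father_id), "0", r$father_id),
          ifelse(is.na(r$mother_id), "0", r$mother_id),
          dplyr::case_match(r$sex, "MALE" ~ "1", "FEMALE" ~ "2", .default = "0"),
          dplyr::case_match(r$affected, "UNAFFECTED" ~ "1", "AFFECTED" ~ "2",
                            .default = "0"),
          ifelse(isTRUE(r$proband), "1", "0"),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

proband_id <- function(ped) ped$id[ped$proband][1]

ped_member <- function(ped, id) ped[!is.na(id) & ped$id == id, ]

# parents of the proband (ids, possibly NA)
proband_parents <- function(ped) {
  p <- ped[ped$proband, ]
  list(father = p$father_id[1], mother = p$mother_id[1])
}

# full siblings of the proband: share both (known) parents
proband_siblings <- function(ped) {
  p <- ped[ped$proband, ]
  if (is.na(p$father_id) && is.na(p$mother_id)) return(character())
  sib <- ped$id != p$id &
    !is.na(ped$father_id) & !is.na(p$father_id) & ped$father_id == p$father_id &
    !is.na(ped$mother_id) & !is.na(p$mother_id) & ped$mother_id == p$mother_id
  ped$id[sib & !is.na(sib)]
}
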