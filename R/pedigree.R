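#' Read a pedigree from a PED/FAM-style file
#'
#' Parses a whitespace- or tab-delimited pedigree file whose first five
#' columns are family ID, individual ID, father ID, mother ID and sex
#' (PLINK PED/FAM convention; extra columns are ignored). `"0"` denotes a
#' missing parent. Sex codes 1/2 are read as male/female; anything else is
#' recorded as unknown.
#'
#' @param path Path to the pedigree file.
#' @param dialect Either `"ped"` or `"fam"`. Both share the first five
#'   columns, so the distinction only documents intent.
#' @return A `fam_pedigree` tibble with columns `fid`, `iid`, `father`,
#'   `mother` (`NA` where missing), `sex` (`"male"`, `"female"`,
#'   `"unknown"`) and `founder`. Row order preserves file order.
#' @export
#' @examples
#' ped_file <- tempfile(fileext = ".ped")
#' writeLines(c("F1 F 0 0 1", "F1 M 0 0 2", "F1 C F M 1"), ped_file)
#' read_pedigree(ped_file)
read_pedigree <- function(path, dialect = c("ped", "fam")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("pedigree file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 5) {
    stop("pedigree file must have at least 5 columns (FID IID PAT MAT SEX), found ",
         ncol(raw), call. = FALSE)
  }
  ped <- tibble::tibble(
    fid = raw[[1]],
    iid = raw[[2]],
    father = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
    mother = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]),
    sex = dplyr::case_match(raw[[5]], "1" ~ "male", "2" ~ "female",
                            .default = "unknown")
  )
  dup <- duplicated(paste(ped$fid, ped$iid, sep = "\r"))
  if (any(dup)) {
    stop("duplicate (FID, IID) pair at line ", which(dup)[1], ": (",
         ped$fid[which(dup)[1]], ", ", ped$iid[which(dup)[1]], ")",
         call. = FALSE)
  }
  new_pedigree(ped)
}

#' Construct and validate a pedigree object
#'
#' @param ped A data frame with columns `fid`, `iid`, `father`, `mother`
#'   and optionally `sex` (missing parents as `NA`).
#' @return A validated `fam_pedigree` tibble (adds `founder`).
#' @export
new_pedigree <- function(ped) {
  ped <- tibble::as_tibble(ped)
  stopifnot(all(c("fid", "iid", "father", "mother") %in% names(ped)))
  if (!"sex" %in% names(ped)) ped$sex <- "unknown"
  if (anyDuplicated(ped$iid)) {
    bad <- ped$iid[duplicated(ped$iid)][1]
    stop("individual IDs must be unique across the pedigree (duplicated: ",
         bad, ")", call. = FALSE)
  }
  self_parent <- !is.na(ped$father) & ped$father == ped$iid |
    !is.na(ped$mother) & ped$mother == ped$iid
  if (any(self_parent)) {
    stop("individual ", ped$iid[which(self_parent)[1]],
         " is listed as its own parent", call. = FALSE)
  }
  ped$founder <- is.na(ped$father) & is.na(ped$mother)
  # parent named in a different family is a structural error
  for (col in c("father", "mother")) {
    p <- ped[[col]]
    idx <- match(p, ped$iid)
    present <- !is.na(p) & !is.na(idx)
    if (any(present & ped$fid[idx] != ped$fid)) {
      bad <- which(present & ped$fid[idx] != ped$fid)[1]
      stop("individual ", ped$iid[bad], " names a ", col,
           " from a different family", call. = FALSE)
    }
  }
  topo_order(ped)  # errors on parentage cycles
  class(ped) <- c("fam_pedigree", class(tibble::tibble()))
  ped
}

# Topological order of individuals (parents before children).
# Errors if the parent graph has a cycle, naming an individual in it.
topo_order <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$iid)
  mo <- match(ped$mother, ped$iid)
  indeg <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stuck <- setdiff(seq_len(n), ord)[1]
    stop("pedigree parentage contains a cycle involving individual ",
         ped$iid[stuck], call. = FALSE)
  }
  ord
}

#' Expected additive kinship matrix of a pedigree
#'
#' Computes pedigree-expected kinship coefficients phi_ij by the standard
#' recursion, processing individuals so parents precede children:
#' phi(f, f) = 1/2 for a non-inbred founder, phi(i, i) = (1 + phi(fa_i,
#' mo_i)) / 2, and phi(i, j) = (phi(fa_i, j) + phi(mo_i, j)) / 2 for j not
#' a descendant of i. Individuals named only as parents are added
#' internally as founders and marginalised out of the result. Members of
#' different families have kinship exactly zero, so the matrix is
#' block-diagonal by family. Autosomal model only; sex is ignored.
#'
#' @param ped A `fam_pedigree` (see [read_pedigree()]).
#' @return A symmetric numeric matrix with the pedigree's individual IDs
#'   as dimnames, in pedigree row order. Twice this matrix (2 Phi) is the
#'   additive relationship matrix used as the polygenic covariance
#'   structure by [fit_null_model()].
#' @export
#' @examples
#' trio <- new_pedigree(data.frame(
#'   fid = "F1", iid = c("F", "M", "C"),
#'   father = c(NA, NA, "F"), mother = c(NA, NA, "M")
#' ))
#' kinship_matrix(trio)
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "fam_pedigree") || is.data.frame(ped))
  # add parents that never appear as rows, as founders of the same family
  missing_parents <- unique(stats::na.omit(c(
    setdiff(ped$father, ped$iid), setdiff(ped$mother, ped$iid)
  )))
  full <- ped
  if (length(missing_parents)) {
    owner <- vapply(missing_parents, function(p) {
      ped$fid[which(ped$father == p | ped$mother == p)[1]]
    }, character(1))
    full <- dplyr::bind_rows(
      tibble::tibble(fid = owner, iid = missing_parents,
                     father = NA_character_, mother = NA_character_,
                     sex = "unknown", founder = TRUE),
      ped
    )
  }
  ids <- full$iid
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  fa <- match(full$father, ids)
  mo <- match(full$mother, ids)
  for (i in topo_order(full)) {
    f <- fa[i]; m <- mo[i]
    pf <- if (is.na(f)) 0 else phi[f, ]
    pm <- if (is.na(m)) 0 else phi[m, ]
    row_i <- (pf + pm) / 2
    phi[i, ] <- row_i
    phi[, i] <- row_i
    phi_fm <- if (is.na(f) || is.na(m)) 0 else phi[f, m]
    phi[i, i] <- (1 + phi_fm) / 2
  }
  phi[ped$iid, ped$iid, drop = FALSE]
}

#' Write a kinship matrix as tab-delimited text
#'
#' Square matrix with a header row of IDs and an ID column.
#'
#' @param K Kinship matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinship matrix written by [write_kinship()]
#'
#' @param path Path to a tab-delimited square matrix with a header row of
#'   IDs and an ID column.
#' @return A symmetric numeric matrix with ID dimnames.
#' @export
read_kinship <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  storage.mode(K) <- "double"
  K
}

#' Write a pedigree in PED format
#'
#' First five PLINK PED columns (FID IID PAT MAT SEX), tab-delimited,
#' missing parents encoded as `"0"` — the dialect [read_pedigree()] reads.
#'
#' @param ped A `fam_pedigree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  sex_code <- dplyr::case_match(ped$sex, "male" ~ "1", "female" ~ "2",
                                .default = "0")
  out <- data.frame(ped$fid, ped$iid,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    sex_code)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
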