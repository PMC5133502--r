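#' Write genes to a minimal VCF
#'
#' Emits a VCF v4.2 with GT-only FORMAT, one record per variant, unphased
#' genotypes reconstructed from dosages (`0/0`, `0/1`, `1/1`, ALT = minor
#' allele). Each gene gets its own CHROM label (the gene ID), so the file
#' round-trips through [read_genotypes_vcf()] without a gene map.
#'
#' @param genes A `fam_gene` or list of them.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genes, path) {
  if (inherits(genes, "fam_gene")) genes <- list(genes)
  samples <- colnames(genes[[1]]$G)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=famcombine",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  ), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (gene in genes) {
    stopifnot(identical(colnames(gene$G), samples))
    for (i in seq_len(nrow(gene$G))) {
      gt <- gt_codes[gene$G[i, ] + 1]
      writeLines(paste(c(gene$gene_id, i, gene$variant_ids[i], "A", "T",
                         ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses GT fields into minor-allele dosage matrices (multi-allelic
#' records and half-calls are not supported; missing calls become `NA`
#' and are mean-imputed by [gene_genotypes()]). Variants are grouped into
#' genes by, in order of preference: a 2-column variant-to-gene map, a
#' 4-column BED-like interval map (chrom, 0-based half-open start/end,
#' gene ID), or failing both, one gene per CHROM value.
#'
#' @param path VCF path.
#' @param gene_map Optional data frame: either columns `variant_id`,
#'   `gene_id`, or columns `chrom`, `start`, `end`, `gene_id` (see
#'   [read_gene_map()]).
#' @return Named list of `fam_gene` objects.
#' @export
read_genotypes_vcf <- function(path, gene_map = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean == "1/1"] <- 2
  fix <- tibble::tibble(
    chrom = vcfR::getCHROM(v),
    pos = vcfR::getPOS(v),
    variant_id = vcfR::getID(v)
  )
  no_id <- is.na(fix$variant_id) | fix$variant_id == "."
  fix$variant_id[no_id] <- paste0(fix$chrom[no_id], ":", fix$pos[no_id])
  rownames(dos) <- fix$variant_id

  assignment <- assign_genes(fix, gene_map)
  genes <- split(assignment$variant_id, assignment$gene_id)
  purrr::imap(genes, function(vars, gid) {
    gene_genotypes(dos[vars, , drop = FALSE], gid)
  })
}

# Map variants to genes. Unassigned variants are dropped with a message.
assign_genes <- function(fix, gene_map) {
  if (is.null(gene_map)) {
    return(tibble::tibble(variant_id = fix$variant_id, gene_id = fix$chrom))
  }
  gene_map <- tibble::as_tibble(gene_map)
  if (all(c("variant_id", "gene_id") %in% names(gene_map))) {
    hit <- dplyr::inner_join(fix["variant_id"],
                             gene_map[c("variant_id", "gene_id")],
                             by = "variant_id")
  } else if (all(c("chrom", "start", "end", "gene_id") %in% names(gene_map))) {
    hit <- dplyr::inner_join(fix, gene_map, by = "chrom",
                             relationship = "many-to-many")
    hit <- hit[hit$pos > hit$start & hit$pos <= hit$end,
               c("variant_id", "gene_id")]
  } else {
    stop("gene_map must have columns (variant_id, gene_id) or ",
         "(chrom, start, end, gene_id)", call. = FALSE)
  }
  dropped <- setdiff(fix$variant_id, hit$variant_id)
  if (length(dropped)) {
    message(length(dropped), " variant(s) not covered by the gene map; dropped")
  }
  hit
}

#' Read a gene map file
#'
#' Tab-delimited, no header: either 2 columns (variant ID, gene ID) or 4
#' BED-like columns (chrom, start, end, gene ID; 0-based half-open).
#'
#' @param path File path.
#' @return A tibble suitable for `gene_map` in [read_genotypes_vcf()].
#' @export
read_gene_map <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(raw) == 2) {
    tibble::tibble(variant_id = raw[[1]], gene_id = raw[[2]])
  } else if (ncol(raw) >= 4) {
    tibble::tibble(chrom = raw[[1]], start = as.integer(raw[[2]]),
                   end = as.integer(raw[[3]]), gene_id = raw[[4]])
  } else {
    stop("gene map must have 2 or 4 columns, found ", ncol(raw),
         call. = FALSE)
  }
}

#' Read a variant-by-sample dosage matrix
#'
#' Tab-delimited with a header line; first column variant IDs, remaining
#' columns one per sample, entries 0/1/2 (missing allowed).
#'
#' @param path File path.
#' @param gene_id Gene label for the returned object.
#' @return A `fam_gene`.
#' @export
read_genotypes_matrix <- function(path, gene_id = "gene") {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  G <- as.matrix(raw[, -1, drop = FALSE])
  rownames(G) <- raw[[1]]
  storage.mode(G) <- "double"
  gene_genotypes(G, gene_id)
}

#' Write a variant-by-sample dosage matrix
#'
#' @param gene A `fam_gene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_matrix <- function(gene, path) {
  df <- data.frame(variant_id = gene$variant_ids, gene$G,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phenotype/covariate table
#'
#' Tab-delimited with a header (ID column first) — the dialect
#' [read_phenotypes()] reads.
#'
#' @param pheno Data frame with an ID column plus trait/covariate columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' @param path Tab-delimited file with a header; one ID column plus
#'   trait/covariate columns.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE))
}
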