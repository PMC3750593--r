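#' Haplotype library of phased high-density individuals
#'
#' Container for the phased chromosomes of the high-density genotyped
#' individuals (typically the Beagle-phased training set plus the sires of
#' the selection candidates). Alleles are 0/1 (`NA` = missing).
#'
#' @param pat,mat integer matrices, individuals x markers, with matching
#'   dimnames: the paternally and maternally inherited allele of each
#'   individual at each marker.
#' @return object of class `haplib`.
#' @export
haplotype_library <- function(pat, mat) {
  stopifnot(is.matrix(pat), is.matrix(mat),
            identical(dim(pat), dim(mat)),
            identical(dimnames(pat), dimnames(mat)))
  if ((nrow(pat) > 0 && is.null(rownames(pat))) || is.null(colnames(pat)))
    stop("haplotype matrices need individual rownames and marker colnames")
  structure(list(pat = pat, mat = mat), class = "haplib")
}

#' @export
print.haplib <- function(x, ...) {
  cat("<haplib> ", nrow(x$pat), " individuals x ", ncol(x$pat),
      " markers (", 2 * nrow(x$pat), " haplotypes)\n", sep = "")
  invisible(x)
}

# dosage implied by the library
haplib_dosage <- function(lib) lib$pat + lib$mat

#' Read genotypes (and phased haplotypes) from a VCF file
#'
#' Parses the GT field of a VCF 4.x file into a dosage matrix, and, where
#' genotypes are phased (`|` separator), into a haplotype library. Positions
#' are converted from 1-based bp to Mb. Only biallelic records are
#' supported; dosages count ALT alleles (re-oriented to the minor allele
#' downstream by [compute_maf()]).
#'
#' @param path VCF file (optionally gzipped).
#' @param require_phased if `TRUE`, any unphased non-missing genotype is an
#'   error naming the offending individual.
#' @return list with `geno` (dosage matrix, individuals x markers), `map`
#'   (marker map data.frame: `marker_id`, `chrom`, `pos_mb`, `known`),
#'   `haplib` (a [haplotype_library()], or `NULL` if nothing is phased).
#' @export
read_vcf_genotypes <- function(path, require_phased = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))                   # single-record VCF
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[is.na(ids) | ids == ".", "CHROM"], "_",
           fix[is.na(ids) | ids == ".", "POS"])
  if (anyDuplicated(ids))
    stop("duplicate marker ids in VCF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rownames(gt) <- ids
  samples <- colnames(gt)

  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  a1[a1 == "."] <- NA; a2[a2 == "."] <- NA
  a1 <- suppressWarnings(matrix(as.integer(a1), nrow(gt), ncol(gt)))
  a2 <- suppressWarnings(matrix(as.integer(a2), nrow(gt), ncol(gt)))
  phased <- sep == "|" & !is.na(a1) & !is.na(a2)

  if (require_phased) {
    bad <- !is.na(a1) & !is.na(a2) & sep != "|"
    if (any(bad)) {
      who <- samples[unique(which(bad, arr.ind = TRUE)[, 2])]
      stop("unphased genotypes where phased data are required, individuals: ",
           paste(who, collapse = ", "))
    }
  }

  dos <- a1 + a2
  geno <- t(dos)
  dimnames(geno) <- list(samples, ids)

  haplib <- NULL
  if (any(phased)) {
    pat <- a1; mat <- a2
    pat[!phased] <- NA; mat[!phased] <- NA
    pat <- t(pat); mat <- t(mat)
    dimnames(pat) <- dimnames(mat) <- list(samples, ids)
    haplib <- haplotype_library(pat, mat)
  }

  map <- data.frame(marker_id = ids,
                    chrom = fix[, "CHROM"],
                    pos_mb = as.numeric(fix[, "POS"]) / 1e6,
                    known = TRUE,
                    stringsAsFactors = FALSE)
  list(geno = geno, map = map, haplib = haplib)
}

#' Write genotypes (optionally phased) to a VCF file
#'
#' Inverse of [read_vcf_genotypes()]: writes a dosage matrix, or a haplotype
#' library when `haplib` is given (phased `a|b` genotypes), as a biallelic
#' VCF. Round-tripping through [read_vcf_genotypes()] reproduces dosages
#' exactly.
#'
#' @param geno dosage matrix (individuals x markers); ignored for phased
#'   output if `haplib` is given.
#' @param map marker map data.frame (`marker_id`, `chrom`, `pos_mb`).
#'   Unplaced markers are written with chromosome `.` and position 0.
#' @param path output path; `.gz` suffix is honoured by vcfR.
#' @param haplib optional [haplotype_library()] to write phased.
#' @export
write_vcf_genotypes <- function(geno, map, path, haplib = NULL) {
  if (!is.null(haplib)) {
    ids <- colnames(haplib$pat)
    samples <- rownames(haplib$pat)
  } else {
    ids <- colnames(geno)
    samples <- rownames(geno)
  }
  map <- map[match(ids, map$marker_id), , drop = FALSE]
  chrom <- ifelse(is.na(map$chrom), ".", map$chrom)
  pos <- ifelse(is.na(map$pos_mb), 0, round(map$pos_mb * 1e6))
  fix <- cbind(CHROM = chrom, POS = as.character(as.integer(pos)),
               ID = ids, REF = "A", ALT = "B", QUAL = ".",
               FILTER = "PASS", INFO = ".")
  if (!is.null(haplib)) {
    gt_body <- matrix(paste0(t(haplib$pat), "|", t(haplib$mat)),
                      nrow = length(ids))
    gt_body[is.na(t(haplib$pat)) | is.na(t(haplib$mat))] <- ".|."
  } else {
    g <- t(geno)
    gt_body <- matrix("./.", nrow(g), ncol(g))
    gt_body[!is.na(g) & g == 0] <- "0/0"
    gt_body[!is.na(g) & g == 1] <- "0/1"
    gt_body[!is.na(g) & g == 2] <- "1/1"
  }
  gt <- cbind(FORMAT = "GT", gt_body)
  colnames(gt) <- c("FORMAT", samples)
  vcf <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = c("##fileformat=VCFv4.2",
                               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                      fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read a tab-separated marker map
#'
#' Columns (header required): `marker_id`, `chrom`, `pos_mb`, `known`
#' (0/1). Chromosome `.`, `0`, `NA` or empty means unknown; such markers
#' carry no position.
#'
#' @param path TSV file.
#' @return marker map data.frame.
#' @export
read_marker_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(marker_id = "character",
                                          chrom = "character"))
  need <- c("marker_id", "chrom", "pos_mb", "known")
  if (!all(need %in% names(map)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker ids in map")
  map$chrom[map$chrom %in% c(".", "0", "", "NA")] <- NA
  map$pos_mb <- as.numeric(map$pos_mb)
  map$pos_mb[is.na(map$chrom)] <- NA
  map$known <- as.logical(as.integer(map$known))
  map[need]
}

#' Write a marker map as TSV
#' @param map marker map data.frame.
#' @param path output file.
#' @export
write_marker_map <- function(map, path) {
  out <- map
  out$chrom[is.na(out$chrom)] <- "."
  out$known <- as.integer(out$known)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree TSV (`id`, `sire`, `dam`; `0` = unknown)
#' @param path TSV file with header.
#' @return an [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  pd <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(pd)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  pedigree(pd$id, pd$sire, pd$dam)
}

#' Read trait records (`id`, `trait`, `ebv`, `reliability`[, `debv`])
#'
#' Reliability is the squared accuracy of the conventional EBV, in (0, 1].
#' Records with reliability 0 are dropped with a warning: they carry no
#' information and their residual weight would be infinite.
#'
#' @param path TSV file with header.
#' @return data.frame of trait records.
#' @export
read_traits <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character", trait = "character"))
  need <- c("id", "trait", "ebv", "reliability")
  if (!all(need %in% names(tr)))
    stop("trait file must have columns: ", paste(need, collapse = ", "))
  bad <- tr$reliability <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with reliability 0 dropped")
    tr <- tr[!bad, , drop = FALSE]
  }
  tr
}

#' Load a complete dataset from files
#'
#' Convenience loader tying the individual readers together and
#' cross-referencing identifiers: genotyped individuals absent from the
#' pedigree and map/VCF marker mismatches are reported.
#'
#' @param vcf high-density VCF (phased GT fills the haplotype library).
#' @param ped pedigree TSV.
#' @param map optional marker map TSV; overrides positions from the VCF
#'   (used to carry `known` flags and approximated positions).
#' @param traits optional trait record TSV.
#' @return list with `geno`, `map`, `ped`, `traits`, `haplib`.
#' @export
load_dataset <- function(vcf, ped, map = NULL, traits = NULL) {
  g <- read_vcf_genotypes(vcf)
  pd <- read_pedigree(ped)
  mp <- if (is.null(map)) g$map else read_marker_map(map)
  if (!setequal(mp$marker_id, colnames(g$geno)))
    stop("marker map and VCF disagree on marker ids")
  mp <- mp[match(colnames(g$geno), mp$marker_id), , drop = FALSE]
  tr <- if (is.null(traits)) NULL else read_traits(traits)
  unknown <- setdiff(rownames(g$geno), pd$id)
  if (length(unknown))
    warning("genotyped individuals absent from pedigree: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) " ..." else "")
  list(geno = g$geno, map = mp, ped = pd, traits = tr, haplib = g$haplib)
}
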