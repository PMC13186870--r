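#' Read a phased VCF into a cohort
#'
#' Reads a VCF v4.2 with phased `GT` fields (separator `|`) into a
#' `triokf_cohort` without pedigree information; attach a pedigree read with
#' [read_ped()] via [attach_pedigree()].  Only biallelic SNV records are
#' supported; an unphased genotype or a multi-allelic record is an error.
#'
#' @param path Path to a VCF file (may be bgzipped).
#' @return A `triokf_cohort` with an empty pedigree.
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    abort("multi-allelic records are not supported.")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field.")
  unphased <- !is.na(gt) & grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    w <- which(unphased, arr.ind = TRUE)[1L, ]
    abort(paste0("unphased genotype at record ", fix$POS[w[1L]],
                 ", sample ", colnames(gt)[w[2L]],
                 ": all GT fields must be phased ('|')."))
  }
  bad <- !is.na(gt) & !gt %in% c("0|0", "0|1", "1|0", "1|1", ".|.")
  if (any(bad)) abort("unsupported GT value; only 0|0, 0|1, 1|0, 1|1, .|. are allowed.")
  samples <- colnames(gt)
  V <- nrow(gt)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  to_int <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out
  }
  haps <- matrix(NA_integer_, 2L * length(samples), V)
  for (s in seq_along(samples)) {
    haps[2L * s - 1L, ] <- to_int(a1[, s])
    haps[2L * s, ] <- to_int(a2[, s])
  }
  variants <- tibble::tibble(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  individuals <- tibble::tibble(id = samples, sex = 0L,
                                phenotype = NA_real_)
  new_cohort(haps, variants, individuals)
}

#' Write a cohort as a phased VCF
#'
#' Writes VCF v4.2 with one phased `GT` column per individual; missing
#' genotypes become `.|.`.  Round-trips losslessly with [read_phased_vcf()]
#' for CHROM/POS/ID/REF/ALT and GT.
#'
#' @param cohort A `triokf_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(cohort, path) {
  vt <- cohort$variants
  n_ind <- nrow(cohort$individuals)
  h1 <- t(cohort$haplotypes[seq(1L, 2L * n_ind, by = 2L), , drop = FALSE])
  h2 <- t(cohort$haplotypes[seq(2L, 2L * n_ind, by = 2L), , drop = FALSE])
  gt <- matrix(paste0(ifelse(is.na(h1), ".", h1), "|",
                      ifelse(is.na(h2), ".", h2)),
               nrow = nrow(vt))
  gt[is.na(h1) | is.na(h2)] <- ".|."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=triokf",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$individuals$id), collapse = "\t")
  )
  body <- paste(vt$chrom, vt$pos, vt$id, vt$ref, vt$alt, ".", "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a 6-column PED/FAM pedigree file
#'
#' Columns: family id, individual id, father id, mother id, sex (1/2/0) and
#' phenotype coded 1 = unaffected, 2 = affected, 0 = missing.
#'
#' @param cohort A `triokf_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(cohort, path) {
  ped <- cohort$pedigree
  ind <- cohort$individuals
  fam <- rep(NA_character_, nrow(ind))
  fa <- rep("0", nrow(ind))
  mo <- rep("0", nrow(ind))
  for (i in seq_len(nrow(ped))) {
    members <- stats::na.omit(c(ped$father[i], ped$mother[i], ped$offspring[i]))
    fam[match(members, ind$id)] <- ped$trio_id[i]
    k <- match(ped$offspring[i], ind$id)
    if (!is.na(ped$father[i])) fa[k] <- ped$father[i]
    if (!is.na(ped$mother[i])) mo[k] <- ped$mother[i]
  }
  fam[is.na(fam)] <- ind$id[is.na(fam)]
  phe <- ifelse(is.na(ind$phenotype), 0L, ind$phenotype + 1L)
  lines <- paste(fam, ind$id, fa, mo, ind$sex, phe, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a 6-column PED/FAM pedigree file
#'
#' @param path Path to a whitespace-delimited 6-column pedigree file.
#' @return Tibble with columns `family`, `id`, `father`, `mother`, `sex`,
#'   `phenotype` (1 affected / 0 unaffected / `NA`).
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "phenotype"),
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "integer", "integer"))
  tibble::tibble(
    family = tab$family, id = tab$id,
    father = ifelse(tab$father == "0", NA_character_, tab$father),
    mother = ifelse(tab$mother == "0", NA_character_, tab$mother),
    sex = tab$sex,
    phenotype = dplyr::case_when(tab$phenotype == 2L ~ 1,
                                 tab$phenotype == 1L ~ 0,
                                 TRUE ~ NA_real_)
  )
}

#' Attach pedigree information to a cohort
#'
#' Resolves trios from a pedigree table: each individual with a recorded
#' parent becomes an offspring of one trio.  Trio type is inferred from the
#' proband: type 1 if the offspring is affected, type 2 if a parent is the
#' only affected proband candidate.
#'
#' @param cohort A `triokf_cohort` (as from [read_phased_vcf()]).
#' @param ped Tibble from [read_ped()].
#' @return The cohort with `individuals$sex`, `individuals$phenotype` and
#'   `pedigree` filled in.
#' @export
attach_pedigree <- function(cohort, ped) {
  idx <- match(cohort$individuals$id, ped$id)
  if (anyNA(idx))
    abort("pedigree file is missing individuals present in the VCF.")
  cohort$individuals$sex <- ped$sex[idx]
  cohort$individuals$phenotype <- ped$phenotype[idx]
  off <- ped[!is.na(ped$father) | !is.na(ped$mother), , drop = FALSE]
  phe <- function(id) {
    if (is.na(id)) return(NA_real_)
    ped$phenotype[match(id, ped$id)]
  }
  rows <- lapply(seq_len(nrow(off)), function(i) {
    o <- off[i, ]
    p_off <- phe(o$id)
    p_fa <- phe(o$father)
    p_mo <- phe(o$mother)
    type <- if (isTRUE(p_off == 1)) 1L
            else if (isTRUE(p_fa == 1) || isTRUE(p_mo == 1)) 2L
            else NA_integer_
    proband <- if (isTRUE(p_off == 1)) o$id
               else if (isTRUE(p_fa == 1)) o$father
               else if (isTRUE(p_mo == 1)) o$mother
               else NA_character_
    tibble::tibble(trio_id = o$family, trio_type = type,
                   father = o$father, mother = o$mother,
                   offspring = o$id, proband = proband)
  })
  cohort$pedigree <- dplyr::bind_rows(rows)
  # validate references
  new_cohort(cohort$haplotypes, cohort$variants, cohort$individuals,
             cohort$pedigree)
}

#' Write a ground-truth transmission sidecar
#'
#' Tab-separated record of the simulated transmissions: one row per
#' (trio, parent, variant) with the transmitted parental haplotype index.
#'
#' @param truth A `triokf_truth` from [simulate_trios()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  long <- function(m, parent) {
    if (is.null(m)) return(NULL)
    df <- expand.grid(trio = truth$trio_id, variant = seq_len(ncol(m)),
                      stringsAsFactors = FALSE)
    df$parent <- parent
    df$transmitted <- as.vector(m)
    df[!is.na(df$transmitted), c("trio", "parent", "variant", "transmitted")]
  }
  out <- rbind(long(truth$transmitted_father, "father"),
               long(truth$transmitted_mother, "mother"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
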