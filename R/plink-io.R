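#' Read a PLINK text fileset into a GenotypePanel
#'
#' Reads whitespace-delimited `.ped`/`.map` files plus a two-column population
#' file (`sample_id<TAB>population`). Genotypes are encoded as dosages of the
#' lexicographically greater of the two alleles observed at each SNP, so a
#' write/read round trip is lossless. `0` is the missing-allele code
#' (a `0 0` genotype becomes `NA`).
#'
#' @param prefix path prefix; `<prefix>.ped`, `<prefix>.map`, `<prefix>.pop`
#'   are read unless the individual paths are given.
#' @param ped_path,map_path,pop_path explicit file paths (override `prefix`).
#' @return A [GenotypePanel-class].
#' @export
readPlinkPanel <- function(prefix = NULL, ped_path = NULL, map_path = NULL,
                           pop_path = NULL) {
  if (!is.null(prefix)) {
    if (is.null(ped_path)) ped_path <- paste0(prefix, ".ped")
    if (is.null(map_path)) map_path <- paste0(prefix, ".map")
    if (is.null(pop_path)) pop_path <- paste0(prefix, ".pop")
  }
  map <- tryCatch(
    read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = c("character", "character", "numeric", "integer")),
    error = function(e) stop("no markers: cannot read map file '", map_path,
                             "' (", conditionMessage(e), ")"))
  if (nrow(map) == 0L) stop("no markers")
  names(map) <- c("chromosome", "snp_id", "cm", "position_bp")
  n_snp <- nrow(map)

  ped <- scan(ped_path, what = character(), quiet = TRUE)
  ncol_exp <- 6L + 2L * n_snp
  if (length(ped) %% ncol_exp != 0L)
    stop("dimension mismatch: .ped has ", length(ped),
         " fields, not a multiple of ", ncol_exp,
         " (6 + 2 x ", n_snp, " markers)")
  ped <- matrix(ped, ncol = ncol_exp, byrow = TRUE)
  sample_id <- ped[, 2L]
  if (anyDuplicated(sample_id))
    stop("duplicate sample id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))

  a1 <- ped[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE]  # samples x snps
  a2 <- ped[, 6L + 2L * seq_len(n_snp), drop = FALSE]
  half <- (a1 == "0") != (a2 == "0")
  if (any(half))
    stop("half-missing genotype (one allele '0') at ", sum(half), " call(s)")

  dosage <- matrix(NA_integer_, n_snp, length(sample_id))
  allele1 <- character(n_snp); allele2 <- character(n_snp)
  for (j in seq_len(n_snp)) {
    g1 <- a1[, j]; g2 <- a2[, j]
    called <- g1 != "0"
    al <- sort(unique(c(g1[called], g2[called])))
    if (length(al) > 2L)
      stop("more than 2 alleles at SNP '", map$snp_id[j], "': ",
           paste(al, collapse = ", "))
    if (length(al) == 0L) { allele1[j] <- "A"; allele2[j] <- NA_character_
    } else if (length(al) == 1L) { allele1[j] <- al; allele2[j] <- NA_character_
    } else { allele1[j] <- al[1L]; allele2[j] <- al[2L] }
    cnt <- rep(NA_integer_, length(g1))
    if (!is.na(allele2[j]))
      cnt[called] <- (g1[called] == allele2[j]) + (g2[called] == allele2[j])
    else
      cnt[called] <- 0L
    dosage[j, ] <- cnt
  }
  dimnames(dosage) <- list(map$snp_id, sample_id)

  pop <- read.table(pop_path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE,
                    col.names = c("sample_id", "population"))
  pops <- setNames(pop$population, pop$sample_id)

  GenotypePanel(dosage,
                map = data.frame(snp_id = map$snp_id,
                                 chromosome = map$chromosome,
                                 position_bp = map$position_bp,
                                 allele1 = allele1, allele2 = allele2,
                                 stringsAsFactors = FALSE),
                populations = pops)
}

#' Write a GenotypePanel as a PLINK text fileset
#'
#' Emits `<prefix>.ped`, `<prefix>.map` (chromosome, snp id, 0 cM, bp) and
#' `<prefix>.pop` (sample id, population). Missing genotypes are written
#' `0 0`; the population label doubles as the family id in the `.ped`.
#'
#' @param panel a [GenotypePanel-class]
#' @param prefix output path prefix
#' @return `prefix`, invisibly.
#' @export
writePlinkPanel <- function(panel, prefix) {
  map <- markerMap(panel)
  write.table(data.frame(map$chromosome, map$snp_id, 0, map$position_bp),
              paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  d <- dosages(panel)
  a1 <- map$allele1
  a2 <- ifelse(is.na(map$allele2), map$allele1, map$allele2)
  n_snp <- nrow(d); n_samp <- ncol(d)
  first <- matrix(a1, n_snp, n_samp)   # snps x samples
  second <- matrix(a1, n_snp, n_samp)
  alt <- matrix(a2, n_snp, n_samp)
  hom2 <- !is.na(d) & d == 2L
  has2 <- !is.na(d) & d >= 1L
  first[hom2] <- alt[hom2]
  second[has2] <- alt[has2]
  first[is.na(d)] <- "0"; second[is.na(d)] <- "0"
  geno <- matrix(paste(first, second), n_snp, n_samp)
  pops <- populations(panel)
  lines <- vapply(seq_len(n_samp), function(i)
    paste(c(pops[i], colnames(d)[i], "0", "0", "0", "-9", geno[, i]),
          collapse = " "), character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  write.table(data.frame(colnames(d), unname(pops)),
              paste0(prefix, ".pop"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
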