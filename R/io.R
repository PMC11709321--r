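## Plain-text exchange formats: profile and SNP TSVs, SFS files, flat
## key-value configs, FASTA/Newick via ape, and report serialization.

#' Read and write site fitness-profile tables
#'
#' TSV with a `site` column (0-based) followed by the 20 amino acids in
#' alphabetical one-letter order, one row per alignment site.
#'
#' @param path file path.
#' @return `read_profiles`: L x 20 matrix.
#' @export
read_profiles <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  stopifnot(all(c("site", AA_LETTERS) %in% names(d)))
  d <- d[order(d$site), ]
  F <- as.matrix(d[AA_LETTERS])
  rownames(F) <- NULL
  F
}

#' @rdname read_profiles
#' @param profiles L x 20 fitness matrix.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(ncol(profiles) == 20)
  d <- data.frame(site = seq_len(nrow(profiles)) - 1L, profiles,
                  check.names = FALSE)
  colnames(d) <- c("site", AA_LETTERS)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write SNP tables
#'
#' TSV dialect with header: `gene`, `site` (0-based alignment codon
#' index), `ancestral_codon`, `derived_codon`, `derived_count`, `n`,
#' `cpg_flag`.
#'
#' @param path file path.
#' @return data frame of SNPs.
#' @export
read_snps <- function(path) {
  d <- read.delim(path)
  need <- c("gene", "site", "ancestral_codon", "derived_codon",
            "derived_count", "n")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("SNP table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"cpg_flag" %in% names(d)) d$cpg_flag <- FALSE
  if (any(d$derived_count < 1 | d$derived_count > d$n - 1))
    stop("derived counts must be in 1..n-1")
  d
}

#' @rdname read_snps
#' @param snps SNP data frame.
#' @export
write_snps <- function(snps, path) {
  write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write SFS files
#'
#' One line per spectrum: `class n L xi_1 ... xi_{n-1}`, whitespace
#' separated.
#'
#' @param path file path.
#' @return named list of [sfs()] objects.
#' @export
read_sfs_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    n <- as.integer(f[2])
    out[[f[1]]] <- sfs(as.numeric(f[-(1:3)]), n, as.numeric(f[3]), f[1])
  }
  out
}

#' @rdname read_sfs_file
#' @param spectra named list of [sfs()] objects.
#' @export
write_sfs_file <- function(spectra, path) {
  lines <- vapply(spectra, function(x)
    paste(c(x$class, x$n, format(x$L, digits = 12),
            format(x$xi, digits = 12)), collapse = " "), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Flat key-value configuration files
#'
#' `key = value` per line; numbers and logicals are auto-typed.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
    else if (val %in% c("TRUE", "FALSE")) as.logical(val)
    else val
  }
  out
}

#' @rdname read_config
#' @param config named list of scalars.
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(lapply(config, format)),
                   sep = " = "), path)
  invisible(path)
}

## integer codon states -> nucleotide strings ("---" for NA)
.codon_strings <- function(states) {
  s <- index_codon(states)
  s[is.na(s)] <- "---"
  s
}

#' Write a codon alignment or exome to FASTA
#'
#' @param aln a [codon_alignment()], or an integer codon vector (written
#'   as a single record named `exome`).
#' @param path file path.
#' @export
write_codon_fasta <- function(aln, path) {
  if (is.null(dim(aln))) aln <- matrix(aln, 1, dimnames = list("exome"))
  seqs <- apply(unclass(aln), 1, function(r)
    paste(.codon_strings(r), collapse = ""))
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Read a codon alignment from FASTA
#'
#' @param path file path.
#' @return a [codon_alignment()].
#' @export
read_codon_fasta <- function(path) {
  codon_alignment(ape::read.FASTA(path))
}

#' Emit every file of a synthetic bundle
#'
#' Writes the scenario config, Newick tree, fitness-profile TSVs (original
#' and post-shift truth), FASTA exomes/alignment, the SNP TSV, and the
#' truth tables, so the pipeline can be exercised through its file-based
#' interfaces.
#'
#' @param bundle a [make_scenario_bundle()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  scen <- bundle$scenario
  write_config(list(n_sites = scen$n_sites, Ne = scen$Ne, u = scen$u,
                    theta = scen$theta, n = scen$n,
                    concentration = scen$concentration,
                    shift_fraction = scen$shift_fraction,
                    mispolarization_rate = scen$mispolarization_rate,
                    cpg_fraction = scen$cpg_fraction,
                    cpg_multiplier = scen$cpg_multiplier,
                    seed = scen$seed, focal = scen$focal),
               p("scenario.conf"))
  ape::write.tree(scen$tree, p("tree.nwk"))
  write_profiles(bundle$profiles, p("profiles.tsv"))
  write_profiles(bundle$profiles_true, p("profiles_true.tsv"))
  write_codon_fasta(bundle$exome, p("exome.fasta"))
  write_codon_fasta(bundle$anc_exome, p("ancestral_exome.fasta"))
  if (!is.null(bundle$alignment))
    write_codon_fasta(bundle$alignment, p("alignment.fasta"))
  write_snps(bundle$snps, p("snps.tsv"))
  write.table(bundle$snp_truth, p("snp_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$substitutions) && nrow(bundle$substitutions))
    write.table(bundle$substitutions, p("substitutions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a class-conditional divergence table
#'
#' TSV with one row per selection class (columns `class`, `D`, `L`, `dN`,
#' `dNdS`) followed by a summary block with `D_syn`, `dS` and the
#' inflation statistic delta(dN/dS).
#'
#' @param tab a [dnds_by_class()] table.
#' @param path file path.
#' @export
write_divergence_table <- function(tab, path) {
  stopifnot(inherits(tab, "divergence_table"))
  con <- file(path, "w")
  on.exit(close(con))
  write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  delta <- tryCatch(delta_dnds(tab), error = function(e) NA_real_)
  writeLines(c("", paste("D_syn", attr(tab, "D_syn"), sep = "\t"),
               paste("dS", attr(tab, "dS"), sep = "\t"),
               paste("delta_dNdS", delta, sep = "\t")), con)
  invisible(path)
}

#' Serialize a selection report
#'
#' Writes a flat TSV of scalars plus per-class blocks, and a JSON mirror
#' for machine reading; seeds and filter toggles are embedded.
#'
#' @param report a [run_pipeline()] result.
#' @param path_prefix output path without extension (writes
#'   `<prefix>.tsv` and `<prefix>.json`).
#' @export
write_report <- function(report, path_prefix) {
  scal <- c(theta_S = report$theta_S, Ne = report$Ne,
            P_B0_given_B = report$recall[["B"]],
            unlist(report$meta))
  tsv <- file.path(paste0(path_prefix, ".tsv"))
  lines <- c(paste("key", "value", sep = "\t"),
             paste(names(scal), unname(scal), sep = "\t"),
             "", paste("class", "P_x", "precision", "recall", sep = "\t"))
  for (x in c("D0", "N0", "B0")) {
    y <- sub("0", "", x)
    lines <- c(lines, paste(x, report$opportunities$P_x[[x]],
                            report$precision[[x]], report$recall[[y]],
                            sep = "\t"))
  }
  writeLines(lines, tsv)
  json <- list(theta_S = report$theta_S, Ne = report$Ne,
               P_x = as.list(report$opportunities$P_x),
               posteriors = report$posteriors,
               precision = as.list(report$precision),
               recall = as.list(report$recall),
               marginal = as.list(report$marginal),
               meta = report$meta)
  jsonlite::write_json(json, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}
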