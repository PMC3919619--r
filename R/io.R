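# Readers and writers for the pipeline's plain-text dialects. Every writer
# round-trips through its reader to numerical identity (full-precision
# numbers; 1e-12 or better).

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read an expression matrix TSV
#'
#' Rows are genes, columns experiment ids, entries log2 ratios; first
#' column header is `gene`.
#'
#' @param values genes x experiments numeric matrix.
#' @param path file path.
#' @return `read_expression_tsv` returns the numeric matrix.
#' @export
write_expression_tsv <- function(values, path) {
  df <- data.frame(gene = rownames(values),
                   apply(values, 2L, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene")
    egr_stop(sprintf("%s: first column must be 'gene'", path),
             "egrinet_parse_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    egr_stop(sprintf("%s: non-numeric expression values", path),
             "egrinet_parse_error")
  rownames(m) <- df$gene
  m
}

#' Write / read experiment metadata TSV
#'
#' Columns: experiment, condition, time, set, deleted_gene (`-` when none).
#' @param meta data frame of experiment metadata.
#' @param path file path.
#' @export
write_metadata_tsv <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("experiment", "condition", "time", "deleted_gene")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    egr_stop(sprintf("%s: missing metadata column '%s'", path, missing[1]),
             "egrinet_parse_error")
  df
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then the member genes,
#' tab-separated.
#' @param sets named list of gene-id vectors.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      egr_stop(sprintf("%s line %d: GMT lines need >= 3 fields", path, i),
               "egrinet_parse_error")
    out[[fields[1]]] <- fields[-(1:2)]
  }
  out
}

#' Write / read promoter sequences as FASTA
#'
#' Record ids are gene ids.
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read position weight matrices in MEME minimal format
#'
#' @param pwms named list of 4 x L probability matrices (rows A, C, G, T).
#' @param path file path.
#' @param background background base frequencies recorded in the header.
#' @export
write_meme_pwms <- function(pwms, path, background = c(A = 0.25, C = 0.25,
                                                       G = 0.25, T = 0.25)) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             paste(sprintf("%s %.5f", names(background), background),
                   collapse = " "), "")
  for (nm in names(pwms)) {
    pwm <- pwms[[nm]]
    lines <- c(lines,
               sprintf("MOTIF %s", nm),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(pwm)),
               apply(t(pwm), 1L, function(row)
                 paste(sprintf("%.6f", row), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_meme_pwms
#' @export
read_meme_pwms <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      nm <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) &&
             !startsWith(lines[j], "letter-probability")) j <- j + 1L
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      mat <- t(vapply(rows, function(r)
        as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4),
        USE.NAMES = FALSE))
      if (any(abs(rowSums(mat) - 1) > 1e-3))
        egr_stop(sprintf("%s: motif %s has rows not summing to 1", path, nm),
                 "egrinet_validation_error")
      pwm <- t(mat)
      rownames(pwm) <- c("A", "C", "G", "T")
      out[[nm]] <- pwm
      i <- j + w
    }
    i <- i + 1L
  }
  out
}

#' Write / read binding events TSV
#'
#' Columns: tf, chrom, position, p_value.
#' @param events data frame of binding events.
#' @param path file path.
#' @export
write_binding_tsv <- function(events, path) {
  events$p_value <- fmt_num(events$p_value)
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binding_tsv
#' @export
read_binding_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "chrom", "position", "p_value")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    egr_stop(sprintf("%s: missing binding column '%s'", path, missing[1]),
             "egrinet_parse_error")
  bad <- which(!is.finite(df$position) | !is.finite(df$p_value))
  if (length(bad) > 0)
    egr_stop(sprintf("%s line %d: malformed binding event", path,
                     bad[1] + 1L), "egrinet_parse_error")
  df
}

#' Write / read gene models TSV (gene, chrom, strand, tss; 1-based)
#' @param gene_models data frame.
#' @param path file path.
#' @export
write_gene_models_tsv <- function(gene_models, path) {
  write.table(gene_models, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models_tsv
#' @export
read_gene_models_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "strand", "tss")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    egr_stop(sprintf("%s: missing gene-model column '%s'", path, missing[1]),
             "egrinet_parse_error")
  df
}

#' Write / read regulatory programs TSV
#'
#' Long format: target, regulator, coefficient, intercept, provenance.
#' Empty programs appear as a single row with regulator `-` and
#' coefficient 0.
#' @param programs named list of `egrin_program`s.
#' @param path file path.
#' @export
write_program_tsv <- function(programs, path) {
  rows <- lapply(programs, function(p) {
    if (length(p$terms) == 0L) {
      data.frame(target = p$target, regulator = "-", coefficient = "0",
                 intercept = fmt_num(p$intercept), provenance = p$provenance,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(target = p$target, regulator = names(p$terms),
                 coefficient = fmt_num(as.numeric(p$terms)),
                 intercept = fmt_num(p$intercept), provenance = p$provenance,
                 stringsAsFactors = FALSE)
    }
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_program_tsv
#' @export
read_program_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("target", "regulator", "coefficient", "intercept", "provenance")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    egr_stop(sprintf("%s: missing program column '%s'", path, missing[1]),
             "egrinet_parse_error")
  out <- lapply(split(df, df$target), function(d) {
    keep <- d$regulator != "-"
    new_program(d$target[1],
                setNames(d$coefficient[keep], d$regulator[keep]),
                d$intercept[1], d$provenance[1])
  })
  class(out) <- c("egrin_program_set", class(out))
  out
}

#' Write / read cluster memberships TSV (cluster_id, gene)
#' @param clusters named list of gene sets.
#' @param path file path.
#' @export
write_cluster_tsv <- function(clusters, path) {
  df <- data.frame(
    cluster_id = rep(names(clusters), lengths(clusters)),
    gene = unlist(clusters, use.names = FALSE), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_tsv
#' @export
read_cluster_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cluster_id", "gene") %in% names(df)))
    egr_stop(sprintf("%s: cluster files need columns cluster_id, gene", path),
             "egrinet_parse_error")
  split(df$gene, df$cluster_id)
}

#' Write an integrated network as SIF plus a JSON attribute table
#'
#' The SIF carries `regulator regulates target` triples; the JSON carries
#' per-edge attributes (condition, streams, weight, direction) keyed by
#' `regulator|target|condition`, loadable alongside the SIF in Cytoscape.
#'
#' @param network integrated edge data frame from [integrate_evidence()].
#' @param sif_path,json_path output paths.
#' @export
write_network_sif <- function(network, sif_path, json_path = NULL) {
  sif <- unique(data.frame(a = network$regulator, rel = "regulates",
                           b = network$target, stringsAsFactors = FALSE))
  write.table(sif, sif_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  if (!is.null(json_path)) {
    attrs <- setNames(
      lapply(seq_len(nrow(network)), function(i)
        list(condition = network$condition[i],
             streams = strsplit(network$streams[i], ",")[[1]],
             n_streams = network$n_streams[i],
             weight = network$weight[i],
             direction = network$direction[i])),
      paste(network$regulator, network$target, network$condition,
            sep = "|"))
    jsonlite::write_json(attrs, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(sif_path)
}

#' Write a ground truth's inputs to a directory
#'
#' Materializes every input the pipeline consumes: expression and metadata
#' TSVs, the annotation GMT, promoter FASTA, MEME motif file, binding and
#' gene-model TSVs, and the true edge list. Purely a serialization of
#' already-generated objects, so a directory is reproducible from
#' (truth, expression, binding) alone.
#'
#' @param truth `egrin_truth`.
#' @param exprs `egrin_expression`.
#' @param binding optional `egrin_binding_sim`.
#' @param dir output directory (created if needed).
#' @return named vector of written file paths.
#' @export
simulate_to_dir <- function(truth, exprs, binding = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    annotations = file.path(dir, "annotations.gmt"),
    edges = file.path(dir, "true_edges.tsv"),
    gene_models = file.path(dir, "gene_models.tsv")
  )
  write_expression_tsv(exprs$values, paths["expression"])
  write_metadata_tsv(exprs$meta, paths["metadata"])
  write_gmt(truth$annotation_sets, paths["annotations"])
  edges <- truth$edges
  edges$beta <- fmt_num(edges$beta)
  write.table(edges, paths["edges"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gene_models_tsv(truth$gene_models, paths["gene_models"])
  if (!is.null(binding)) {
    paths <- c(paths,
               promoters = file.path(dir, "promoters.fasta"),
               motifs = file.path(dir, "motifs.meme"),
               binding = file.path(dir, "binding.tsv"))
    write_fasta(binding$promoters, paths["promoters"])
    write_meme_pwms(binding$pwms, paths["motifs"])
    write_binding_tsv(binding$events, paths["binding"])
  }
  paths
}
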