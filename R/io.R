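## Tabular I/O, configuration serialization and provenance logging.
## All tables are plain TSV; gene positions use BED (0-based half-open).

#' Read a gene-by-sample count matrix
#'
#' Reads a TSV whose first column (`gene`) holds gene identifiers and the
#' remaining columns integer counts, together with a sample sheet mapping
#' each sample to its metadata (`sample` plus e.g. `species`,
#' `population`, `tissue`, `accession`).  Samples missing from the sheet
#' are rejected rather than silently kept.
#'
#' @param path TSV file of counts.
#' @param sampleSheet TSV file with a `sample` column; optional.
#' @return An [ExpressionCounts-class] object.
#' @export
readCountMatrix <- function(path, sampleSheet = NULL) {
    tab <- tryCatch(read.delim(path, check.names = FALSE),
                    error = function(e) stop("malformed count file: ",
                                             conditionMessage(e)))
    if (nrow(tab) == 0 || ncol(tab) < 2)
        stop("count file must have a gene-id column and >= 1 sample column")
    if (!"gene" %in% colnames(tab)[1])
        stop("first column of a count file must be named 'gene'")
    genes <- as.character(tab[[1]])
    if (anyDuplicated(genes)) stop("duplicate gene ids in count file")
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts")
    if (anyNA(m) || any(m < 0) || any(m != round(m)))
        stop("counts must be non-negative integers")
    rownames(m) <- genes
    sd <- NULL
    if (!is.null(sampleSheet)) {
        sheet <- read.delim(sampleSheet, check.names = FALSE)
        if (!"sample" %in% colnames(sheet))
            stop("sample sheet needs a 'sample' column")
        missing <- setdiff(colnames(m), sheet$sample)
        if (length(missing))
            stop("samples without metadata: ", paste(missing, collapse = ", "))
        sheet <- sheet[match(colnames(m), sheet$sample), , drop = FALSE]
        sd <- DataFrame(sheet[setdiff(colnames(sheet), "sample")],
                        row.names = colnames(m))
    }
    ExpressionCounts(m, sampleData = sd)
}

#' Read phased homeologue counts
#'
#' Long-format TSV with columns `gene`, `accession`, `count_co`,
#' `count_cg`.  (gene, accession) pairs absent from the file become `NA`
#' in the matrices, never zero.
#'
#' @param path TSV file.
#' @return A [PhasedCounts-class] object.
#' @export
readPhasedCounts <- function(path) {
    tab <- read.delim(path, check.names = FALSE)
    need <- c("gene", "accession", "count_co", "count_cg")
    if (!all(need %in% colnames(tab)))
        stop("phased count file needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab[, c("gene", "accession")]))
        stop("duplicate (gene, accession) rows in phased counts")
    genes <- unique(as.character(tab$gene))
    acc <- unique(as.character(tab$accession))
    co <- matrix(NA_real_, length(genes), length(acc),
                 dimnames = list(genes, acc))
    cg <- co
    i <- cbind(match(tab$gene, genes), match(tab$accession, acc))
    co[i] <- tab$count_co
    cg[i] <- tab$count_cg
    PhasedCounts(co, cg)
}

#' Read gene positions from a BED file
#'
#' BED coordinates are 0-based half-open; the returned
#' [GenomicRanges::GRanges] follows the usual 1-based closed convention,
#' so widths and midpoints are unambiguous.
#'
#' @param path BED file (first four columns: chrom, start, end, name).
#' @return A `GRanges` with gene ids as names.
#' @export
readGenePositions <- function(path) {
    tab <- read.delim(path, header = FALSE)
    if (ncol(tab) < 4) stop("BED file needs chrom, start, end, name")
    if (any(tab[[2]] > tab[[3]])) stop("BED start > end")
    gr <- GRanges(as.character(tab[[1]]),
                  IRanges(start = tab[[2]] + 1L, end = pmax(tab[[3]], tab[[2]] + 1L)))
    names(gr) <- as.character(tab[[4]])
    gr
}

#' @rdname readGenePositions
#' @param gr a `GRanges` with gene names.
#' @export
writeGenePositions <- function(gr, path) {
    tab <- data.frame(chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1L, end = end(gr),
                      name = names(gr))
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write an analysis table deterministically
#'
#' Columns are emitted in their existing order, floats at fixed
#' precision, so identical inputs give byte-identical files.  The output
#' directory is created if absent.
#'
#' @param results a data.frame.
#' @param path destination TSV.
#' @param digits significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
writeReport <- function(results, path, digits = 6) {
    stopifnot(is.data.frame(results))
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    out <- results
    for (j in seq_along(out))
        if (is.double(out[[j]]))
            out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
    con <- file(path, open = "wb")  # fixed EOL across platforms
    on.exit(close(con))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n")
    invisible(path)
}

.configFields <- c("fdr_threshold", "pseudo_count", "bootstrap_reps",
                   "rng_seed", "de_engine", "tissues")

#' Serialize / load a RunConfig
#'
#' The on-disk format is a flat YAML document; unknown keys are an error
#' so that typos are caught instead of silently ignored.
#'
#' @param config a [RunConfig-class].
#' @param path YAML file.
#' @return `readRunConfig` returns a `RunConfig`; `writeRunConfig` its
#'   `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
    stopifnot(is(config, "RunConfig"))
    yaml::write_yaml(list(fdr_threshold = config@fdrThreshold,
                          pseudo_count = config@pseudoCount,
                          bootstrap_reps = config@bootstrapReps,
                          rng_seed = config@rngSeed,
                          de_engine = config@deEngine,
                          tissues = as.list(config@tissues)), path)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), .configFields)
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    def <- RunConfig()
    RunConfig(fdrThreshold = vals$fdr_threshold %||% def@fdrThreshold,
              pseudoCount = vals$pseudo_count %||% def@pseudoCount,
              bootstrapReps = vals$bootstrap_reps %||% def@bootstrapReps,
              rngSeed = vals$rng_seed %||% def@rngSeed,
              deEngine = vals$de_engine %||% def@deEngine,
              tissues = unlist(vals$tissues) %||% def@tissues)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Provenance record for a run
#'
#' @param config a [RunConfig-class].
#' @param inputs character vector of input file paths (checksummed).
#' @return A data.frame of key/value provenance entries: package version,
#'   seed, config hash and md5 of each input.
#' @export
provenanceLog <- function(config, inputs = character()) {
    tmp <- tempfile(fileext = ".yaml")
    writeRunConfig(config, tmp)
    entries <- data.frame(
        key = c("package_version", "rng_seed", "config_md5",
                if (length(inputs)) paste0("input_md5:", basename(inputs))),
        value = c(as.character(packageVersion("homeoExpress")),
                  as.character(config@rngSeed),
                  unname(tools::md5sum(tmp)),
                  if (length(inputs)) unname(tools::md5sum(inputs))),
        stringsAsFactors = FALSE)
    unlink(tmp)
    entries
}
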