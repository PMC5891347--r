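`%||%` <- function(a, b) if (is.null(a)) b else a

.centroid <- function(xyz) colMeans(xyz)

## Write a data.frame as TSV with '#'-prefixed header metadata lines.
.writeTSV <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = " "),
                              character(1))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTSV <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

## Square whitespace-delimited matrix with residue-index header row/column.
.writeSquareMatrix <- function(M, resno, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = " "),
                              character(1))), con)
  writeLines(paste(c("resno", resno), collapse = " "), con)
  for (i in seq_along(resno))
    writeLines(paste(c(resno[i], format(M[i, ], digits = 10)), collapse = " "),
               con)
  invisible(path)
}

.readSquareMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  resno <- as.integer(header[-1])
  body <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  M <- body[, -1, drop = FALSE]
  dimnames(M) <- NULL
  list(resno = resno, matrix = M)
}

## Metadata header shared by all pipeline outputs.
.outputMeta <- function(config = NULL, extra = list()) {
  meta <- list(package = paste("DomainDynamics",
                               as.character(utils::packageVersion("DomainDynamics"))))
  if (!is.null(config)) {
    meta$config_hash <- .configHash(config)
    meta$temperature_K <- config@temperature
  }
  c(meta, extra)
}

.configHash <- function(config) {
  snap <- .configSnapshot(config)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(snap, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

.configSnapshot <- function(config) {
  list(domains = config@domains, helices = config@helices,
       salt_bridges = config@saltBridges, pca_residue_range = config@pcaRange,
       temperature = config@temperature, chain = config@chain,
       frame_interval_ps = config@frameInterval,
       production_length_ns = config@productionLength,
       n_replicas = config@nReplicas, parameters = config@params)
}

## Run a block with a temporarily-seeded RNG, restoring the caller's state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}
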