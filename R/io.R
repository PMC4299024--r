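#' @include AllClasses.R config.R
NULL

## All writers emit a small provenance header as '#'-prefixed comment lines
## (package version, creation timestamp, seed where applicable); readers
## skip them. Numeric fields are written with %.17g so every reader/writer
## pair round-trips doubles exactly.

provenanceHeader <- function(kind, extra = character()) {
  c(sprintf("# actseg %s", kind),
    sprintf("# version: %s",
            as.character(utils::packageVersion("actseg"))),
    if (length(extra)) paste0("# ", names(extra), ": ", extra))
}

fmtNum <- function(x) ifelse(is.finite(x), sprintf("%.17g", x),
                             as.character(x))   # "-Inf" survives re-parsing

writeCsvWithHeader <- function(df, path, kind, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceHeader(kind, extra), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

readCsvSkippingHeader <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a triaxial recording as CSV
#'
#' Format: header \code{timestamp,x,y,z}, one row per sample, acceleration
#' in g, preceded by '#' provenance comment lines.
#'
#' @param recording a \code{\link{TriaxialRecording}}.
#' @param path CSV file path.
#' @return \code{path} invisibly (writer); a \code{TriaxialRecording}
#'   (reader).
#' @export
writeRecordingCSV <- function(recording, path) {
  df <- data.frame(timestamp = fmtNum(recording@time),
                   x = fmtNum(recording@x), y = fmtNum(recording@y),
                   z = fmtNum(recording@z))
  writeCsvWithHeader(df, path, "signal", c(run_id = recording@runId))
}

#' @rdname writeRecordingCSV
#' @param run_id run identifier to attach (reader; defaults to the file
#'   name without extension).
#' @export
readRecordingCSV <- function(path, run_id = sub("\\.[^.]*$", "", basename(path))) {
  df <- readCsvSkippingHeader(path)
  need <- c("timestamp", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("malformed signal CSV ", path, ": need columns ",
         paste(need, collapse = ","))
  TriaxialRecording(run_id, df$timestamp, df$x, df$y, df$z)
}

#' Write / read an activity labeling as CSV
#'
#' Format: header \code{start,end,activity}; half-open, non-overlapping
#' intervals on the recording's clock.
#'
#' @param labeling an \code{\link{ActivityLabeling}}.
#' @param path CSV file path.
#' @return \code{path} invisibly (writer); an \code{ActivityLabeling}
#'   (reader).
#' @export
writeLabelingCSV <- function(labeling, path) {
  df <- data.frame(start = fmtNum(labeling@start), end = fmtNum(labeling@end),
                   activity = labeling@activity)
  writeCsvWithHeader(df, path, "labels", c(run_id = labeling@runId))
}

#' @rdname writeLabelingCSV
#' @export
readLabelingCSV <- function(path, run_id = sub("\\.[^.]*$", "", basename(path))) {
  df <- readCsvSkippingHeader(path)
  need <- c("start", "end", "activity")
  if (!all(need %in% names(df)))
    stop("malformed label CSV ", path, ": need columns ",
         paste(need, collapse = ","))
  ActivityLabeling(run_id, df$start, df$end, df$activity)
}

#' Write / read a codebook
#'
#' The centroids go to \code{<prefix>.csv} (one centroid per row) and a JSON
#' sidecar \code{<prefix>.json} stores M, the seed and the feature order.
#'
#' @param codebook a \code{\link{Codebook}}.
#' @param prefix path prefix (without extension).
#' @return \code{prefix} invisibly (writer); a \code{Codebook} (reader).
#' @export
writeCodebook <- function(codebook, prefix) {
  df <- as.data.frame(apply(codebook@centroids, 2L, fmtNum))
  names(df) <- codebook@featureOrder
  writeCsvWithHeader(df, paste0(prefix, ".csv"), "codebook")
  jsonlite::write_json(list(M = nrow(codebook@centroids),
                            seed = codebook@seed,
                            feature_order = codebook@featureOrder),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname writeCodebook
#' @export
readCodebook <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- readCsvSkippingHeader(paste0(prefix, ".csv"))
  centroids <- as.matrix(df)
  colnames(centroids) <- meta$feature_order
  methods::new("Codebook", centroids = centroids,
               seed = as.integer(meta$seed),
               featureOrder = meta$feature_order)
}

#' Write / read primitive sequences
#'
#' Format: \code{run_id,position,primitive,label,time}, one row per window
#' position, possibly several runs per file.
#'
#' @param seqs a \code{\link{PrimitiveSequence}} or list of them.
#' @param path CSV file path.
#' @return \code{path} invisibly (writer); a list of
#'   \code{PrimitiveSequence} (reader).
#' @export
writePrimitiveSequences <- function(seqs, path) {
  if (!is.list(seqs)) seqs <- list(seqs)
  df <- do.call(rbind, lapply(seqs, function(s)
    data.frame(run_id = runId(s), position = seq_len(nSamples(s)),
               primitive = primitives(s), label = activityLabels(s),
               time = fmtNum(s@time))))
  M <- alphabetSize(seqs[[1]])
  writeCsvWithHeader(df, path, "primitive-sequences", c(M = M))
}

#' @rdname writePrimitiveSequences
#' @export
readPrimitiveSequences <- function(path) {
  df <- readCsvSkippingHeader(path)
  # the alphabet size travels in the provenance header
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  mLine <- grep("^# M: ", hdr, value = TRUE)
  M <- if (length(mLine)) as.integer(sub("^# M: ", "", mLine[1])) else max(df$primitive)
  lapply(split(df, df$run_id), function(d) {
    d <- d[order(d$position), ]
    PrimitiveSequence(d$run_id[1], d$primitive, labels = d$label,
                      time = d$time, M = M)
  })
}

#' Write / read a fitted sequence model
#'
#' Scalars and small arrays (states, M, k, kappa, weights, alpha, pi, the
#' per-state k-mer defaults) go to \code{<prefix>.json}; A and B are CSV
#' matrices; the k-mer table is a sparse CSV \code{state,kmer,logp} of
#' observed k-mers only.
#'
#' @param model a \code{\link{SequenceModel}}.
#' @param prefix path prefix (without extension).
#' @return \code{prefix} invisibly (writer); a \code{SequenceModel}
#'   (reader).
#' @export
writeModel <- function(model, prefix) {
  jsonlite::write_json(
    list(states = model@states, M = model@M, k = model@kmerK,
         kappa = model@kappa, weights = model@weights, alpha = model@alpha,
         pi = fmtNum(model@pi),
         kmer_default = fmtNum(vapply(model@kmerLogp, `[[`, numeric(1),
                                      "default")),
         kmer_n_positions = vapply(model@kmerLogp, function(tab)
           if (is.null(tab$n_positions)) NA_integer_ else
             as.integer(tab$n_positions), integer(1)),
         kmer_lambda = fmtNum(vapply(model@kmerLogp, function(tab)
           if (is.null(tab$lambda)) 1 else tab$lambda, numeric(1)))),
    paste0(prefix, ".json"), auto_unbox = FALSE, digits = NA)
  writeCsvWithHeader(as.data.frame(apply(model@A, 2L, fmtNum)),
                     paste0(prefix, "_A.csv"), "transition-matrix")
  writeCsvWithHeader(as.data.frame(apply(model@B, 2L, fmtNum)),
                     paste0(prefix, "_B.csv"), "emission-matrix")
  rows <- do.call(rbind, lapply(seq_along(model@states), function(i) {
    lp <- model@kmerLogp[[i]]$logp
    if (!length(lp)) return(NULL)
    data.frame(state = model@states[i], kmer = names(lp), logp = fmtNum(lp))
  }))
  writeCsvWithHeader(rows, paste0(prefix, "_kmers.csv"), "kmer-table")
  invisible(prefix)
}

#' @rdname writeModel
#' @export
readModel <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  A <- as.matrix(readCsvSkippingHeader(paste0(prefix, "_A.csv")))
  B <- as.matrix(readCsvSkippingHeader(paste0(prefix, "_B.csv")))
  dimnames(A) <- list(meta$states, meta$states)
  dimnames(B) <- list(meta$states, NULL)
  km <- readCsvSkippingHeader(paste0(prefix, "_kmers.csv"))
  kmerLogp <- lapply(seq_along(meta$states), function(i) {
    d <- km[km$state == meta$states[i], ]
    list(logp = stats::setNames(as.numeric(d$logp), as.character(d$kmer)),
         default = as.numeric(meta$kmer_default[i]), n_obs = nrow(d),
         n_positions = if (!is.null(meta$kmer_n_positions))
           as.integer(meta$kmer_n_positions[i]) else NULL,
         lambda = if (!is.null(meta$kmer_lambda))
           as.numeric(meta$kmer_lambda[i]) else NULL)
  })
  names(kmerLogp) <- meta$states
  methods::new("SequenceModel", states = meta$states,
               M = as.integer(meta$M), A = A, B = B,
               pi = as.numeric(meta$pi), kmerK = as.integer(meta$k),
               kmerLogp = kmerLogp, kappa = as.integer(meta$kappa),
               weights = as.numeric(meta$weights),
               alpha = as.numeric(meta$alpha))
}

#' Write / read a subclass map
#'
#' Format: \code{subclass,original_class} plus the per-instance assignment
#' block in \code{<prefix>_assignments.csv}.
#'
#' @param subclass_map a \code{\link{SubclassMap}}.
#' @param prefix path prefix (without extension).
#' @return \code{prefix} invisibly (writer); a \code{SubclassMap} (reader).
#' @export
writeSubclassMap <- function(subclass_map, prefix) {
  writeCsvWithHeader(
    data.frame(subclass = subclass_map@map$subclass,
               original_class = subclass_map@map$original),
    paste0(prefix, ".csv"), "subclass-map")
  writeCsvWithHeader(subclass_map@assignments,
                     paste0(prefix, "_assignments.csv"),
                     "subclass-assignments")
  invisible(prefix)
}

#' @rdname writeSubclassMap
#' @export
readSubclassMap <- function(prefix) {
  m <- readCsvSkippingHeader(paste0(prefix, ".csv"))
  a <- readCsvSkippingHeader(paste0(prefix, "_assignments.csv"))
  frag <- table(factor(m$original_class, levels = unique(m$original_class)))
  methods::new("SubclassMap",
               map = data.frame(subclass = m$subclass,
                                original = m$original_class),
               fragments = stats::setNames(as.integer(frag), names(frag)),
               assignments = a)
}

#' Write per-day accuracies, pooled confusion and sensitivities
#'
#' @param results one method's entry from \code{\link{leaveOneDayOut}}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
writeEvaluation <- function(results, prefix) {
  writeCsvWithHeader(data.frame(day = names(results$perDay),
                                accuracy = fmtNum(results$perDay)),
                     paste0(prefix, "_perday.csv"), "per-day-accuracy")
  conf <- as.data.frame.matrix(results$confusion)
  conf <- cbind(truth = rownames(results$confusion), conf)
  writeCsvWithHeader(conf, paste0(prefix, "_confusion.csv"),
                     "pooled-confusion")
  writeCsvWithHeader(data.frame(class = names(results$sensitivity),
                                sensitivity = fmtNum(results$sensitivity)),
                     paste0(prefix, "_sensitivity.csv"), "sensitivity")
  invisible(prefix)
}
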