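# Versioned text serialization of trained bundles: a one-line JSON header
# (format, version, md5 of the payload text) followed by a pretty-printed
# JSON payload.  Log-probabilities survive the round trip at full double
# precision (serialized with >= 15 significant digits).

BUNDLE_FORMAT <- "transcds-bundle"
BUNDLE_VERSION <- 1L

num <- function(x) {
  # JSON-safe numeric: jsonlite writes non-finite values as strings, and
  # as.numeric() maps them back, so -Inf round-trips
  as.numeric(x)
}

chainToList <- function(m) {
  list(type = "chain", order = m@order, logProb = num(m@logProb),
       pseudocount = m@pseudocount)
}

emissionToList <- function(e) {
  if (is(e, "MarkovChainModel")) return(chainToList(e))
  if (is(e, "PeriodicMarkovModel"))
    return(list(type = "periodic", phases = lapply(e@phases, chainToList)))
  if (is(e, "PositionalModel"))
    return(list(type = "positional", windowStart = e@windowStart,
                logProbs = num(e@logProbs), len = nrow(e@logProbs)))
  stop("unknown emission model class")
}

emissionFromList <- function(x) {
  switch(x$type,
    chain = markovChainModel(x$order,
                             matrix(asNum(x$logProb), ncol = 4L),
                             x$pseudocount),
    periodic = do.call(periodicMarkovModel,
                       lapply(x$phases, emissionFromList)),
    positional = {
      m <- new("PositionalModel", windowStart = as.integer(x$windowStart),
               logProbs = matrix(asNum(x$logProbs), nrow = x$len))
      colnames(m@logProbs) <- DNA_BASES4
      validObject(m)
      m
    },
    stop("unknown emission type in bundle: ", x$type))
}

# "-Inf"/"Inf"/"NA" strings (jsonlite's encoding of non-finite values in
# numeric arrays) coerce back silently
asNum <- function(x) {
  v <- unlist(x)
  if (is.null(v)) return(numeric(0))
  suppressWarnings(as.numeric(v))
}

stateToList <- function(s) {
  list(name = s@name, durationKind = s@durationKind,
       fixedLen = s@fixedLen, selfLoopLogP = num(s@selfLoopLogP),
       inPhase = s@inPhase, congruence = s@congruence,
       requiredCodons = as.list(s@requiredCodons),
       noInternalStops = s@noInternalStops,
       emission = emissionToList(s@emission),
       flankUp = if (is.null(s@flankUp)) NULL else emissionToList(s@flankUp),
       flankDown = if (is.null(s@flankDown)) NULL else
         emissionToList(s@flankDown),
       duration = if (is.null(s@duration)) NULL else
         list(minLen = s@duration@minLen, maxLen = s@duration@maxLen,
              step = s@duration@step, logPmf = num(s@duration@logPmf),
              tailLogP = num(s@duration@tailLogP),
              tailLogMass = num(s@duration@tailLogMass)))
}

stateFromList <- function(x) {
  dur <- if (is.null(x$duration)) NULL else
    durationModel(x$duration$minLen, x$duration$maxLen,
                  asNum(x$duration$logPmf),
                  tailLogMass = asNum(x$duration$tailLogMass),
                  tailLogP = asNum(x$duration$tailLogP),
                  step = x$duration$step)
  asInt1 <- function(v)
    if (is.null(v)) NA_integer_ else suppressWarnings(as.integer(v))
  ghmmState(x$name, emissionFromList(x$emission), x$durationKind,
            fixedLen = asInt1(x$fixedLen),
            duration = dur,
            selfLoopLogP = asNum(x$selfLoopLogP),
            inPhase = x$inPhase,
            congruence = asInt1(x$congruence),
            requiredCodons = as.character(unlist(x$requiredCodons)),
            noInternalStops = isTRUE(x$noInternalStops),
            flankUp = if (is.null(x$flankUp)) NULL else
              emissionFromList(x$flankUp),
            flankDown = if (is.null(x$flankDown)) NULL else
              emissionFromList(x$flankDown))
}

archToList <- function(a) {
  list(states = lapply(unname(a@states), stateToList),
       transLog = num(a@transLog), initLog = num(a@initLog),
       finalLog = num(a@finalLog))
}

archFromList <- function(x) {
  states <- lapply(x$states, stateFromList)
  S <- length(states)
  ghmmArchitecture(states, matrix(asNum(x$transLog), S, S),
                   asNum(x$initLog), asNum(x$finalLog))
}

#' Save a trained bundle as versioned text
#'
#' @param bundle a [TrainedBundle-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @seealso [loadBundle()]
#' @export
saveBundle <- function(bundle, path) {
  payload <- list(gcBreaks = bundle@gcBreaks,
                  metadata = bundle@metadata,
                  bins = lapply(bundle@bins, function(b)
                    list(full = archToList(b$full),
                         partial = archToList(b$partial))))
  txt <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                          pretty = TRUE, null = "null")
  header <- sprintf('{"format": "%s", "version": %d, "md5": "%s"}',
                    BUNDLE_FORMAT, BUNDLE_VERSION, md5OfText(txt))
  con <- file(path, open = "wb")   # binary mode: byte-stable line endings
  on.exit(close(con))
  writeLines(c(header, txt), con, sep = "\n")
  invisible(path)
}

md5OfText <- function(txt) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, open = "wb")
  writeLines(txt, con, sep = "\n")
  close(con)
  unname(tools::md5sum(tmp))
}

#' Load a trained bundle
#'
#' Verifies the format header, version and payload checksum before
#' reconstructing the models; a truncated or edited file fails with a
#' checksum error, a bundle from a different format version with a
#' version error.
#'
#' @param path file written by [saveBundle()].
#' @return a [TrainedBundle-class].
#' @export
loadBundle <- function(path) {
  if (!file.exists(path)) stop("bundle file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("truncated bundle file: ", path)
  header <- tryCatch(jsonlite::fromJSON(lines[1]),
                     error = function(e) stop("malformed bundle header"))
  if (!identical(header$format, BUNDLE_FORMAT))
    stop("not a model bundle file: ", path)
  if (!identical(as.integer(header$version), BUNDLE_VERSION))
    stop("bundle version mismatch: file has ", header$version,
         ", this build reads ", BUNDLE_VERSION)
  payloadTxt <- paste(lines[-1], collapse = "\n")
  if (!identical(md5OfText(payloadTxt), header$md5))
    stop("bundle checksum error: file is truncated or was edited")
  payload <- jsonlite::fromJSON(payloadTxt, simplifyVector = FALSE)
  md <- payload$metadata
  md$binCounts <- as.integer(unlist(md$binCounts))
  if (any(md$binCounts < 0L))
    stop("bundle validation error: negative training count")
  bins <- lapply(payload$bins, function(b)
    list(full = archFromList(b$full), partial = archFromList(b$partial)))
  bundle <- new("TrainedBundle", gcBreaks = asNum(payload$gcBreaks),
                bins = bins, metadata = md)
  validObject(bundle)
  bundle
}
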