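# Path analytics: per-step fitness traces, segment traces, identity curves,
# ensemble summaries and minmax path selection.

#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

# Map source-coordinate segments forward through the edit history: returns,
# per step, the current position of every source residue (NA once deleted).
sourcePositionMaps <- function(path) {
  steps <- unname(as.character(pathSteps(path)))
  edits <- pathEdits(path)
  L0 <- nchar(steps[1L])
  cur <- seq_len(L0)
  maps <- vector("list", length(steps))
  maps[[1L]] <- cur
  for (i in seq_len(nrow(edits))) {
    kind <- edits$kind[i]; pos <- edits$position[i]
    if (kind == "insertion") {
      cur <- ifelse(!is.na(cur) & cur >= pos, cur + 1L, cur)
    } else if (kind == "deletion") {
      cur <- ifelse(!is.na(cur) & cur == pos, NA_integer_,
                    ifelse(!is.na(cur) & cur > pos, cur - 1L, cur))
    }
    maps[[i + 1L]] <- cur
  }
  maps
}

normalizeSegments <- function(segments) {
  if (is.null(segments)) return(NULL)
  if (is(segments, "IRanges")) {
    nm <- names(segments) %||% paste0("segment", seq_along(segments))
    segments <- stats::setNames(lapply(seq_along(segments), function(i)
      c(IRanges::start(segments)[i], IRanges::end(segments)[i])), nm)
  }
  if (is.null(names(segments)))
    names(segments) <- paste0("segment", seq_along(segments))
  segments
}

#' Trace per-step metrics along a path
#'
#' For every step: whole-sequence pseudo-perplexity, percent identity to the
#' source and to the target, proximity to the target, sequence length, and
#' (optionally) the pseudo-perplexity of named segments. Segments are given
#' in SOURCE coordinates and carried through indels by mapping each source
#' residue's current position via the edit history; a segment whose residues
#' are all deleted is recorded as `NA`, never an error.
#'
#' @param model a [FitnessModel-class]
#' @param path a [MutationPath-class]
#' @param segments named list of `c(start, end)` pairs (or an `IRanges`) in
#'   source coordinates
#' @param mode alignment mode for the identity/proximity columns
#' @param estimator profile estimator
#' @return an `S4Vectors::DataFrame` with one row per step and metadata
#'   recording the backend, estimator and mode
#' @export
tracePath <- function(model, path, segments = NULL,
                      mode = c("identity", "embedding"),
                      estimator = c("ofs", "masked")) {
  mode <- match.arg(mode); estimator <- match.arg(estimator)
  segments <- normalizeSegments(segments)
  steps <- unname(as.character(pathSteps(path)))
  source <- steps[1L]; target <- steps[length(steps)]
  maps <- if (!is.null(segments)) sourcePositionMaps(path)
  n <- length(steps)
  pp <- numeric(n); idS <- numeric(n); idT <- numeric(n); prox <- numeric(n)
  segCols <- if (!is.null(segments))
    stats::setNames(rep(list(rep(NA_real_, n)), length(segments)),
                    paste0("pp_", names(segments)))
  for (i in seq_len(n)) {
    s <- steps[i]
    prof <- profilesFor(model, s, estimator)
    pp[i] <- ppValue(pseudoPerplexity(prof, s))
    idS[i] <- percentIdentity(s, source, mode, model)
    idT[i] <- percentIdentity(s, target, mode, model)
    prox[i] <- proximityTo(s, target, mode, model)
    if (!is.null(segments)) {
      for (sn in names(segments)) {
        rng <- segments[[sn]]
        mapped <- maps[[i]][rng[1L]:rng[2L]]
        mapped <- mapped[!is.na(mapped)]
        if (length(mapped) > 0L)
          segCols[[paste0("pp_", sn)]][i] <- ppValue(
            segmentPseudoPerplexity(prof, s, c(min(mapped), max(mapped))))
      }
    }
  }
  out <- DataFrame(step = seq_len(n) - 1L, pp = pp,
                   identity_source = idS, identity_target = idT,
                   proximity = prox, length = nchar(steps))
  for (sn in names(segCols)) out[[sn]] <- segCols[[sn]]
  metadata(out) <- list(modelId = modelId(model), estimator = estimator,
                        mode = mode, strategy = path@metadata$strategy)
  out
}

#' Select the path minimising the maximum of a trace column
#'
#' The bottleneck ("minmax") selection: among a set of paths, the one whose
#' largest per-step value of the chosen trace column (e.g. a C-terminal
#' domain's pseudo-perplexity) is smallest. Ties break by fewer steps, then
#' by input order.
#'
#' @param paths list of [MutationPath-class] objects
#' @param traces matching list of traces from [tracePath()]
#' @param column trace column to minimise the maximum of (default `"pp"`)
#' @return the selected path, with `minmaxValue` and `minmaxIndex` added to
#'   its metadata
#' @export
minmaxSelect <- function(paths, traces, column = "pp") {
  if (length(paths) == 0L) stop("no paths to select from", call. = FALSE)
  if (length(paths) != length(traces))
    stop("paths and traces must have equal length", call. = FALSE)
  maxima <- vapply(traces, function(t) {
    if (!column %in% colnames(t))
      stop("trace has no column '", column, "'", call. = FALSE)
    v <- t[[column]]
    if (all(is.na(v))) Inf else max(v, na.rm = TRUE)
  }, numeric(1L))
  nSteps <- vapply(traces, nrow, integer(1L))
  best <- order(maxima, nSteps)[1L]
  out <- paths[[best]]
  out@metadata$minmaxValue <- maxima[best]
  out@metadata$minmaxIndex <- best
  out
}

#' Per-step sequence identity to both endpoints
#'
#' @param path a [MutationPath-class]
#' @param source,target endpoints (default: the path's own)
#' @param mode alignment mode
#' @param model backend for embedding mode
#' @return `data.frame` with columns `step`, `identity_source`,
#'   `identity_target`
#' @export
identityCurve <- function(path, source = NULL, target = NULL,
                          mode = c("identity", "embedding"), model = NULL) {
  mode <- match.arg(mode)
  steps <- unname(as.character(pathSteps(path)))
  source <- source %||% steps[1L]
  target <- target %||% steps[length(steps)]
  data.frame(
    step = seq_along(steps) - 1L,
    identity_source = vapply(steps, percentIdentity, numeric(1L), b = source,
                             mode = mode, model = model, USE.NAMES = FALSE),
    identity_target = vapply(steps, percentIdentity, numeric(1L), b = target,
                             mode = mode, model = model, USE.NAMES = FALSE))
}

#' Summarise an ensemble of traces on a normalised step axis
#'
#' Paths of different lengths are compared on the fraction-of-path-completed
#' axis: each trace's column is linearly interpolated onto a common grid and
#' the per-fraction median and min/max envelope reported, together with each
#' path's maximum value and step count. With a single trace the grid
#' coincides with its own steps and the summary reproduces it exactly.
#'
#' @param traces list of traces from [tracePath()]
#' @param column summarised column (default `"pp"`)
#' @param nGrid number of grid points (default: the largest step count among
#'   the traces)
#' @return list with `grid` (`data.frame`: fraction, median, min, max) and
#'   `perPath` (`data.frame`: path, maxValue, nSteps)
#' @export
ensembleSummary <- function(traces, column = "pp", nGrid = NULL) {
  if (length(traces) == 0L) stop("no traces", call. = FALSE)
  vals <- lapply(traces, function(t) t[[column]])
  lens <- vapply(vals, length, integer(1L))
  nGrid <- as.integer(nGrid %||% max(lens))
  grid <- if (nGrid == 1L) 0 else seq(0, 1, length.out = nGrid)
  onGrid <- vapply(vals, function(v) {
    if (length(v) == 1L) return(rep(v, nGrid))
    stats::approx(seq(0, 1, length.out = length(v)), v, xout = grid,
                  rule = 2)$y
  }, numeric(nGrid))
  onGrid <- matrix(onGrid, nrow = nGrid)
  list(
    grid = data.frame(fraction = grid,
                      median = apply(onGrid, 1L, stats::median),
                      min = apply(onGrid, 1L, min),
                      max = apply(onGrid, 1L, max)),
    perPath = data.frame(path = seq_along(traces),
                         maxValue = vapply(vals, max, numeric(1L)),
                         nSteps = lens))
}

#' Write a trace (or any tabular result) as TSV
#'
#' @param trace a trace `DataFrame` or `data.frame`
#' @param file output path
#' @return `file`, invisibly
#' @export
writeTraceTsv <- function(trace, file) {
  utils::write.table(as.data.frame(trace), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

readTraceTsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE)
}
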