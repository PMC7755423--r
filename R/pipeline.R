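.pipelineDefaults <- list(
  scheme = "parsed", bufferWidth = 3L,
  properties = c("charge", "hydrophobicity1"),
  property = "charge", R = 1000L, alpha = 0.05,
  method = "top_diff", k = 75L, correlationThreshold = 0.75,
  seed = 1L, out = "immunomatrix_out")

.loadConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.pipelineDefaults, config %||% list())
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.prepEncoded <- function(cfg) {
  if (is.null(cfg$input)) stop("config must name an input CSV")
  rec <- readRepertoire(cfg$input, schema = cfg$schema)
  if (!all(is.na(rec$reactivity_count)))
    rec <- assignPolyreactivityLabels(rec, scheme = cfg$scheme)
  encodeRepertoire(rec, bufferWidth = cfg$bufferWidth)
}

#' Run one stage of the repertoire-analysis pipeline
#'
#' Orchestrates the package's modules behind a single entry point with a
#' serialized configuration, for use from scripts and the bundled
#' command-line wrapper (\code{inst/scripts/immunomatrix-cli.R}).
#' Subcommands: \code{encode} (CSV in, integer matrix + JSON sidecar
#' out), \code{profile} (position significance profile of one property
#' mask), \code{entropy} / \code{mi} (per-class entropy profile /
#' mutual-information matrices and their class difference),
#' \code{classify} (feature build, SVM LOOCV report, discriminant
#' weights), \code{mhc} (platform-domain FASTA encoding), and
#' \code{simulate} (synthetic repertoire emission in the same CSV schema
#' the reader consumes). The full configuration, including the seed, is
#' written into the output directory for provenance; all randomness
#' derives from the single configured seed.
#'
#' @param subcommand one of encode, profile, entropy, mi, classify,
#'   mhc, simulate.
#' @param config named list or path to a YAML config. Common fields:
#'   \code{input}, \code{scheme}, \code{bufferWidth},
#'   \code{properties}, \code{R}, \code{alpha}, \code{k},
#'   \code{correlationThreshold}, \code{seed}, \code{out}.
#' @return invisibly, a named character vector of artifact paths.
#' @export
runPipeline <- function(subcommand = c("encode", "profile", "entropy",
                                       "mi", "classify", "mhc",
                                       "simulate"),
                        config = list()) {
  subcommand <- match.arg(subcommand)
  cfg <- .loadConfig(config)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(c(list(subcommand = subcommand), cfg),
                   file.path(cfg$out, "run_config.yaml"))
  set.seed(cfg$seed)
  artifacts <- character()
  message("[immunomatrix] ", subcommand, " (seed ", cfg$seed, ") -> ",
          cfg$out)

  if (subcommand == "simulate") {
    spec <- fixtureSpec(
      nPoly = cfg$nPoly %||% 100L, nNon = cfg$nNon %||% 100L,
      background = cfg$background %||% "uniform",
      shifts = cfg$shifts %||% list(),
      couplings = cfg$couplings %||% list(),
      labelNoise = cfg$labelNoise %||% 0,
      bufferWidth = cfg$bufferWidth)
    gen <- generateRepertoire(spec, seed = cfg$seed)
    p <- file.path(cfg$out, "repertoire.csv")
    utils::write.csv(gen$records[, c("id", .LOOP_NAMES,
                                     "reactivity_count", "source")],
                     p, row.names = FALSE)
    artifacts["repertoire"] <- p
    return(invisible(artifacts))
  }

  if (subcommand == "mhc") {
    classes <- loadPlatformClasses(unlist(cfg$fasta), cfg$roles %||% "train")
    em <- encodePlatform(classes, cfg$boundaries,
                         bufferWidth = cfg$bufferWidth)
    p <- file.path(cfg$out, "platform_matrix.csv")
    writeEncodedMatrix(em, p)
    artifacts["matrix"] <- p
    return(invisible(artifacts))
  }

  em <- .prepEncoded(cfg)

  if (subcommand == "encode") {
    p <- file.path(cfg$out, "encoded_matrix.csv")
    writeEncodedMatrix(em, p)
    artifacts["matrix"] <- p
  } else if (subcommand == "profile") {
    masked <- applyMask(em, cfg$property)
    prof <- profileSignificance(masked, R = cfg$R, alpha = cfg$alpha,
                                seed = cfg$seed)
    p <- file.path(cfg$out, paste0("profile_", cfg$property, ".csv"))
    writeProfile(prof, p)
    artifacts["profile"] <- p
  } else if (subcommand == "entropy") {
    res <- miMatrix(em)
    p <- file.path(cfg$out, "entropy.csv")
    utils::write.csv(data.frame(position = names(res$entropy),
                                entropy_bits = unname(res$entropy)),
                     p, row.names = FALSE)
    artifacts["entropy"] <- p
  } else if (subcommand == "mi") {
    labs <- as.character(rowLabels(em))
    classes <- unique(labs)[1:2]
    for (cl in classes) {
      p <- file.path(cfg$out, paste0("mi_", gsub("\\W", "_", cl), ".csv"))
      writeMIMatrix(miMatrix(em, class = cl)$mi, p)
      artifacts[paste0("mi_", cl)] <- p
    }
    if (!any(is.na(classes))) {
      dm <- miDifferenceWithSignificance(em, classes = classes,
                                         R = cfg$R, seed = cfg$seed)
      p <- file.path(cfg$out, "mi_difference.csv")
      writeMIMatrix(dm$deltaMI, p)
      p2 <- file.path(cfg$out, "mi_difference_p.csv")
      writeMIMatrix(dm$p, p2)
      artifacts["mi_difference"] <- p
      artifacts["mi_difference_p"] <- p2
    }
  } else if (subcommand == "classify") {
    feat <- buildFeatureMatrix(em, cfg$properties, standardize = FALSE)
    labs <- rowLabels(em)
    report <- svmLoocv(feat, labs, k = cfg$k,
                       correlationThreshold = cfg$correlationThreshold,
                       seed = cfg$seed)
    sel <- selectFeatures(feat, labs, method = cfg$method, k = cfg$k,
                          correlationThreshold = cfg$correlationThreshold)
    lda <- ldaFitProject(sel$features, labs)
    segs <- columnSegments(matrixLayout(em))
    tw <- topWeights(lda, k = 10L)
    twCol <- as.integer(sub(".*@", "", tw$feature))
    weights <- data.frame(property = sub("@.*", "", tw$feature),
                          column = twCol, segment = segs[twCol + 1L],
                          weight = tw$weight)
    p <- file.path(cfg$out, "classifier_report.json")
    jsonlite::write_json(list(
      settings = report$settings, seed = cfg$seed,
      loocv_accuracy = report$accuracy,
      lda_separation_accuracy = lda$accuracy,
      predictions = report$predictions), p, auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
    p2 <- file.path(cfg$out, "discriminant_weights.csv")
    utils::write.csv(weights, p2, row.names = FALSE)
    artifacts["report"] <- p
    artifacts["weights"] <- p2
  }
  invisible(artifacts)
}
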