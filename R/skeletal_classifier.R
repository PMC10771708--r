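#' Skeletal classification rules
#'
#' Sagittal class is read off ANB alone: Class I for 1 <= ANB <= 5 degrees,
#' Class II above 5, Class III below 1. Vertical type uses a 2-of-3 quorum
#' over SN-MP, FH-MP (FMA) and FHR:
#' hypodivergent \{SN-MP < 24, FH-MP < 22, FHR > 65\},
#' normodivergent \{24 <= SN-MP <= 36, 22 <= FH-MP <= 30, 62 <= FHR <= 65\},
#' hyperdivergent \{SN-MP > 36, FH-MP > 30, FHR < 62\}.
#' Hypodivergent (short-face) patients have the *larger* posterior-anterior
#' face height ratio, so the FHR bands run opposite to the two mandibular
#' plane angles. Boundary values belong to the band whose inequality is
#' inclusive. When two vertical categories tie at the quorum (possible only
#' on band boundaries) the normodivergent category wins, else the category
#' containing the SN-MP value.
#'
#' @param quorum How many of the three vertical criteria must hold (2 or 3).
#' @return A `ceph_rules` list with elements `sagittal` (band edges) and
#'   `vertical` (per-category criterion bands) and `quorum`.
#' @export
classification_rules <- function(quorum = 2L) {
  stopifnot(quorum %in% c(2L, 3L))
  structure(list(
    sagittal = list(I_low = 1, I_high = 5),   # II: ANB > 5; III: ANB < 1
    vertical = list(
      hypo  = list(SN_MP = c(-Inf, 24), FH_MP = c(-Inf, 22), FHR = c(65, Inf),
                   closed = c(FALSE, FALSE, FALSE)),
      nor   = list(SN_MP = c(24, 36), FH_MP = c(22, 30), FHR = c(62, 65),
                   closed = c(TRUE, TRUE, TRUE)),
      hyper = list(SN_MP = c(36, Inf), FH_MP = c(30, Inf), FHR = c(-Inf, 62),
                   closed = c(FALSE, FALSE, FALSE))
    ),
    quorum = as.integer(quorum)
  ), class = "ceph_rules")
}

#' Serialize / load classification rules as YAML
#'
#' @param rules A `ceph_rules` object.
#' @param path YAML file path.
#' @return `write_rules()` returns `path` invisibly; `read_rules()` a
#'   `ceph_rules` object.
#' @export
write_rules <- function(rules, path) {
  plain <- unclass(rules)
  # YAML has no Inf literal portable across parsers; encode as strings
  plain$vertical <- lapply(plain$vertical, function(v) {
    v$SN_MP <- as.character(v$SN_MP); v$FH_MP <- as.character(v$FH_MP)
    v$FHR <- as.character(v$FHR); v
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  plain <- yaml::read_yaml(path)
  plain$vertical <- lapply(plain$vertical, function(v) {
    v$SN_MP <- as.numeric(v$SN_MP); v$FH_MP <- as.numeric(v$FH_MP)
    v$FHR <- as.numeric(v$FHR); v$closed <- as.logical(v$closed); v
  })
  plain$quorum <- as.integer(plain$quorum)
  structure(plain, class = "ceph_rules")
}

# is x inside [lo, hi] (closed) or outside-the-shared-boundary bands: for the
# open hypo/hyper bands the finite edge is exclusive so that the inclusive
# normodivergent band owns its printed boundaries
.in_band <- function(x, band, closed) {
  if (closed) x >= band[1] & x <= band[2] else x > band[1] & x < band[2]
}

#' Classify the sagittal jaw relationship from ANB
#'
#' @param ANB ANB angle(s) in degrees.
#' @param rules A `ceph_rules` object.
#' @return Character vector in `{"I", "II", "III"}`.
#' @export
classify_sagittal <- function(ANB, rules = classification_rules()) {
  if (any(!is.finite(ANB))) stop("ANB must be finite", call. = FALSE)
  lo <- rules$sagittal$I_low; hi <- rules$sagittal$I_high
  ifelse(ANB < lo, "III", ifelse(ANB > hi, "II", "I"))
}

# per-category criterion count for one observation
.vertical_counts <- function(SN_MP, FH_MP, FHR, rules) {
  vapply(names(rules$vertical), function(cat) {
    v <- rules$vertical[[cat]]
    sum(.in_band(SN_MP, v$SN_MP, v$closed[1]),
        .in_band(FH_MP, v$FH_MP, v$closed[2]),
        .in_band(FHR, v$FHR, v$closed[3]))
  }, integer(1))
}

#' Classify the vertical growth pattern by the 2-of-3 quorum rule
#'
#' @param SN_MP SN-MP angle(s), degrees.
#' @param FH_MP FH-MP (FMA) angle(s), degrees.
#' @param FHR Posterior-anterior face height ratio(s), percent.
#' @inheritParams classify_sagittal
#' @return Character vector in `{"hypo", "nor", "hyper", "unclassified"}`.
#' @export
classify_vertical <- function(SN_MP, FH_MP, FHR, rules = classification_rules()) {
  n <- length(SN_MP)
  stopifnot(length(FH_MP) == n, length(FHR) == n)
  if (any(!is.finite(c(SN_MP, FH_MP, FHR)))) {
    stop("vertical classification inputs must be finite", call. = FALSE)
  }
  out <- character(n)
  for (i in seq_len(n)) {
    counts <- .vertical_counts(SN_MP[i], FH_MP[i], FHR[i], rules)
    hit <- names(counts)[counts >= rules$quorum]
    out[i] <- if (length(hit) == 1L) {
      hit
    } else if (length(hit) == 0L) {
      "unclassified"
    } else if ("nor" %in% hit) {
      "nor"  # boundary tie: prefer the normodivergent band
    } else {
      # remaining tie: the category whose SN-MP band contains the value
      sn_hit <- hit[vapply(hit, function(cat) {
        v <- rules$vertical[[cat]]
        .in_band(SN_MP[i], v$SN_MP, v$closed[1])
      }, logical(1))]
      if (length(sn_hit) >= 1L) sn_hit[1] else hit[1]
    }
  }
  out
}

#' Classify every record of a cohort
#'
#' @param cohort A `ceph_cohort`.
#' @inheritParams classify_sagittal
#' @return A list with `labels` (tibble `id`, `sagittal`, `vertical`),
#'   `table` (sagittal x vertical contingency table including an
#'   `unclassified` column), and, when the cohort carries generator truth
#'   labels, `agreement` — the fraction of records whose predicted cell
#'   matches the intended cell.
#' @export
classify_cohort <- function(cohort, rules = classification_rules()) {
  labels <- tibble::tibble(
    id = cohort$id,
    sagittal = classify_sagittal(cohort$ANB, rules),
    vertical = classify_vertical(cohort$SN_MP, cohort$FH_MP, cohort$FHR, rules)
  )
  tab <- table(
    factor(labels$sagittal, levels = SAGITTAL_LEVELS),
    factor(labels$vertical, levels = c(VERTICAL_LEVELS, "unclassified"))
  )
  truth <- cohort_labels(cohort)
  agreement <- NULL
  if (!is.null(truth)) {
    agreement <- mean(labels$sagittal == truth$sagittal &
                        labels$vertical == truth$vertical)
  }
  list(labels = labels, table = tab, agreement = agreement)
}
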