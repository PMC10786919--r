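.registryCache <- new.env(parent = emptyenv())

#' Residue property registry
#'
#' Loads the residue registry shipped with the package (an editable JSON
#' table mapping each sequence token to its chirality, formal side-chain
#' charge at pH 7.4, polarity class, Eisenberg-scale hydrophobicity, helix
#' propensity class and staple-arm flag). D-enantiomer entries (\code{dX})
#' are derived from the parent L entry: same charge, polarity and
#' hydrophobicity, chirality \code{"D"}. The charge model follows standard
#' formal charges at pH 7.4: Asp/Glu/alpha-methyl-Glu -1, Gla -2 (two
#' side-chain carboxylates), Lys/Arg/homo-Arg +1, His 0 (pKa ~ 6), azido-Lys
#' 0 (the azide removes the amine), staple arms 0.
#'
#' @param path optional path to an alternative registry JSON.
#' @return data.frame with one row per registered code.
#' @export
residueRegistry <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    if (!is.null(.registryCache$reg)) return(.registryCache$reg)
    path <- system.file("extdata", "residues.json", package = "stapleSAR")
  }
  raw <- jsonlite::fromJSON(path)$residues
  dd <- raw[raw$chirality == "L", ]
  dd$code <- paste0("d", dd$code)
  dd$chirality <- "D"
  reg <- rbind(raw, dd)
  rownames(reg) <- reg$code
  if (default) .registryCache$reg <- reg
  reg
}

.resProp <- function(codes, field) {
  reg <- residueRegistry()
  bad <- setdiff(codes, reg$code)
  if (length(bad))
    stop("unknown residue token(s): ", paste(unique(bad), collapse = ", "))
  reg[codes, field]
}

#' Parse extended peptide notation
#'
#' Grammar: an optional name prefix is not part of the notation; the string
#' itself is \code{<cap>-<body>-<cap>} where the N-cap is \code{Ac} (acetyl)
#' or \code{H} (free amine), the C-cap is \code{NH2} (amide) or \code{OH}
#' (free acid), and the body is a run of one-letter codes and bracketed
#' multi-character tokens, e.g. \code{"Ac-LTF[R8]EYWAQL[S5]AAAAA[dA]-NH2"}.
#' Both caps are mandatory: terminal state changes the net charge by a full
#' unit and is never defaulted silently.
#'
#' Staples formed by dedicated arm residues are inferred from the tokens:
#' an \code{[R8]}/\code{[S5]} pair is an i,i+7 olefin staple, an
#' \code{[S5]}/\code{[S5]} pair an i,i+4 olefin staple, and an
#' \code{[X]}/\code{[X]} pair the rigid i,i+7 di-alkyne staple. Crosslinks
#' between proteinogenic side chains (a Lys-Glu lactam bridge, a triazole)
#' carry no dedicated arm token and are declared via \code{staples}; lactam
#' bridging consumes both side-chain charges.
#'
#' @param notation sequence string.
#' @param name peptide identifier.
#' @param staples optional list of \code{list(positions = c(i, j),
#'   chemistry = "lactam"|"triazole")} entries for crosslinks without arm
#'   tokens.
#' @return A [Peptide-class] object. \code{formatPeptide(parsePeptide(s))}
#'   reproduces the canonical notation.
#' @examples
#' p <- parsePeptide("Ac-LTF[R8]EYWAQL[S5]AAAAA[dA]-NH2", name = "ALRN-6924")
#' netCharge(p)
#' @export
parsePeptide <- function(notation, name = "", staples = NULL) {
  s <- trimws(notation)
  if (!nzchar(s)) stop("empty sequence notation")
  if (startsWith(s, "Ac-")) { ncap <- "acetyl"; s <- substring(s, 4) }
  else if (startsWith(s, "H-")) { ncap <- "free"; s <- substring(s, 3) }
  else stop("missing N-terminal cap annotation ('Ac-' or 'H-')")
  if (endsWith(s, "-NH2")) { ccap <- "amide"; s <- substring(s, 1, nchar(s) - 4) }
  else if (endsWith(s, "-OH")) { ccap <- "free_acid"; s <- substring(s, 1, nchar(s) - 3) }
  else stop("missing C-terminal cap annotation ('-NH2' or '-OH')")
  if (!nzchar(s)) stop("empty residue body")

  codes <- character()
  i <- 1L
  chars <- strsplit(s, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unterminated '[' token in notation")
      tok <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!nzchar(tok)) stop("empty '[]' token in notation")
      codes <- c(codes, tok)
      i <- j + 1L
    } else if (grepl("^[A-Z]$", ch)) {
      codes <- c(codes, ch)
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in notation")
    }
  }

  reg <- residueRegistry()
  bad <- setdiff(codes, reg$code)
  if (length(bad))
    stop("unknown residue token(s): ", paste(unique(bad), collapse = ", "))

  armIdx <- which(reg[codes, "is_staple_residue"])
  stDf <- data.frame(pos1 = integer(), pos2 = integer(),
                     chemistry = character(), span = integer(),
                     stringsAsFactors = FALSE)
  if (length(armIdx)) {
    if (length(armIdx) %% 2L != 0L)
      stop("odd number of staple arm residues (", length(armIdx),
           "): inconsistent with any registered staple chemistry")
    for (k in seq(1L, length(armIdx), by = 2L)) {
      p1 <- armIdx[k]; p2 <- armIdx[k + 1L]
      pair <- sort(codes[c(p1, p2)])
      chem <-
        if (identical(pair, c("R8", "S5"))) "olefin_i7"
        else if (identical(pair, c("S5", "S5"))) "olefin_i4"
        else if (identical(pair, c("X", "X"))) "dialkyne"
        else stop("staple arm pair ", paste(codes[c(p1, p2)], collapse = "/"),
                  " matches no registered staple chemistry")
      stDf <- rbind(stDf, data.frame(pos1 = p1, pos2 = p2, chemistry = chem,
                                     span = p2 - p1, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(staples)) {
    for (sp in staples) {
      pos <- sort(as.integer(sp$positions))
      stDf <- rbind(stDf, data.frame(pos1 = pos[1], pos2 = pos[2],
                                     chemistry = sp$chemistry,
                                     span = pos[2] - pos[1],
                                     stringsAsFactors = FALSE))
    }
  }
  new("Peptide", name = name, residues = codes, nTermCap = ncap,
      cTermCap = ccap, staples = stDf)
}

#' Canonical notation for a peptide
#'
#' @param peptide a [Peptide-class] object.
#' @return character scalar; round-trips through [parsePeptide()].
#' @export
formatPeptide <- function(peptide) {
  toks <- vapply(peptide@residues, function(cd)
    if (nchar(cd) > 1L) paste0("[", cd, "]") else cd, character(1))
  paste0(if (peptide@nTermCap == "acetyl") "Ac-" else "H-",
         paste(toks, collapse = ""),
         if (peptide@cTermCap == "amide") "-NH2" else "-OH")
}

setMethod("show", "Peptide", function(object) {
  cat("Peptide", if (nzchar(object@name)) paste0("'", object@name, "'") else "",
      "(", length(object@residues), "residues )\n")
  cat(" ", formatPeptide(object), "\n")
  if (nrow(object@staples))
    cat("  staples:", paste(sprintf("%s %d-%d", object@staples$chemistry,
                                    object@staples$pos1, object@staples$pos2),
                            collapse = "; "), "\n")
  cat("  net charge:", netCharge(object), "\n")
})

#' @describeIn parsePeptide number of residues.
#' @export
peptideLength <- function(peptide) length(peptide@residues)

#' @describeIn parsePeptide residue code vector.
#' @export
peptideResidues <- function(peptide) peptide@residues

#' Net formal charge at pH 7.4
#'
#' Sums side-chain formal charges over all residues plus the terminal
#' contributions (free N-terminus +1, acetyl 0; free-acid C-terminus -1,
#' amide 0). Staple arm residues carry no charge, and side chains consumed
#' by a lactam bridge (the bridging Lys and Glu) contribute 0 because the
#' amide bond removes both ionizable groups.
#'
#' @param peptide a [Peptide-class] object.
#' @return integer net charge.
#' @export
netCharge <- function(peptide) {
  q <- .resProp(peptide@residues, "side_chain_charge")
  st <- peptide@staples
  if (nrow(st)) {
    consumed <- unlist(st[st$chemistry == "lactam", c("pos1", "pos2")])
    if (length(consumed)) q[consumed] <- 0L
  }
  total <- sum(q) +
    (if (peptide@nTermCap == "free") 1L else 0L) +
    (if (peptide@cTermCap == "free_acid") -1L else 0L)
  as.integer(total)
}

#' Ideal alpha-helical wheel projection
#'
#' Places residue k at angle (k-1) * 100 degrees modulo 360 (ideal
#' alpha-helix, 3.6 residues per turn) and attaches each residue's polarity
#' class. Residues 100 degrees apart in sequence index land on the same
#' helical face; the projection is independent of the terminal caps.
#'
#' @param peptide a [Peptide-class] object of length >= 2.
#' @return data.frame with columns \code{index}, \code{code}, \code{angle}
#'   (degrees in [0, 360)) and \code{polarity}.
#' @export
helicalWheel <- function(peptide) {
  n <- peptideLength(peptide)
  if (n < 2L) stop("helical wheel needs at least 2 residues")
  data.frame(index = seq_len(n),
             code = peptide@residues,
             angle = ((seq_len(n) - 1L) * 100) %% 360,
             polarity = .resProp(peptide@residues, "polarity_class"),
             stringsAsFactors = FALSE)
}

#' Helical hydrophobic moment
#'
#' Magnitude of the vector sum of per-residue hydrophobicities placed at the
#' ideal-helix wheel angles (100 degrees per residue), normalized per
#' residue. An amphipathic sequence (hydrophobic residues segregated to one
#' face) has a large moment; a compositionally uniform sequence has a moment
#' near zero. Invariant under a global rotation of the wheel.
#'
#' @param peptide a [Peptide-class] object.
#' @param window optional integer range of residue indices to restrict to.
#' @return non-negative numeric scalar (scale units per residue).
#' @export
hydrophobicMoment <- function(peptide, window = NULL) {
  n <- peptideLength(peptide)
  idx <- if (is.null(window)) seq_len(n) else as.integer(window)
  if (!length(idx)) stop("empty window")
  if (any(idx < 1L | idx > n)) stop("window outside sequence")
  h <- .resProp(peptide@residues[idx], "hydrophobicity")
  th <- (idx - 1L) * 100 * pi / 180
  sqrt(sum(h * cos(th))^2 + sum(h * sin(th))^2) / length(idx)
}

#' C-terminal tail of a stapled peptide
#'
#' The residues following the second (C-terminal-most) staple arm, i.e. the
#' extension whose helical propensity governs cellular activity in the tail
#' series.
#'
#' @param peptide a [Peptide-class] object with at least one staple.
#' @return character vector of residue codes (possibly empty).
#' @export
tailResidues <- function(peptide) {
  st <- peptide@staples
  if (!nrow(st)) stop("peptide has no staple; tail undefined")
  cut <- max(st$pos2)
  if (cut >= peptideLength(peptide)) return(character())
  peptide@residues[(cut + 1L):peptideLength(peptide)]
}

#' Predicted aqueous helical propensity class of a C-terminal tail
#'
#' Classifies a tail as \code{"low"} when it contains any residue of low
#' intrinsic helix propensity (Gly, Pro, sarcosine, in either chirality) or
#' a D-residue at a non-C-terminal position; otherwise \code{"high"}. A
#' single C-terminal D-residue (the protease-protecting cap used in
#' poly-Ala tails) does not break the helix and keeps the class high. The
#' rule reproduces every printed label in the reference tail series (see
#' [tailSeriesData()]).
#'
#' @param tail a [Peptide-class] object, or a character vector of residue
#'   codes as returned by [tailResidues()].
#' @return \code{"high"} or \code{"low"}.
#' @export
classifyTailPropensity <- function(tail) {
  codes <- if (is(tail, "Peptide")) tail@residues else as.character(tail)
  if (!length(codes)) stop("empty tail")
  lowProp <- .resProp(codes, "helix_propensity_class") == "low"
  chir <- .resProp(codes, "chirality")
  internalD <- chir == "D" & seq_along(codes) < length(codes)
  if (any(lowProp) || any(internalD)) "low" else "high"
}
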