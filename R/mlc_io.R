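#' Read a control-point MLC sequence ("dva") file
#'
#' Parses the package's line-oriented `key = value` MLC sequence dialect
#' (documented in `vignette("log-based-imrt-qa")`). The dialect is a
#' self-contained stand-in for vendor shaped-MLC sequence files: a header
#' (`File Rev`, `Plan ID`, `Beam ID`, `Total MU`, `Gantry`,
#' `Number of Fields`) followed by one block per control point
#' (`Index = <0..1>`, then `Leaf 1A` ... `Leaf 60A`, `Leaf 1B` ...
#' `Leaf 60B`, positions in cm with 3 decimals, signed on the leaf-travel
#' axis: bank A tips are typically negative, bank B positive).
#'
#' @param path path to the file.
#' @param geometry leaf bank geometry the file is interpreted against.
#' @return a [dynamic_beam()] with positions in mm at isocenter.
#' @export
read_mlc_file <- function(path, geometry = leaf_bank_geometry()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^\\s*([^=]*?)\\s*=\\s*(.*?)\\s*$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_,
                 character(1))
  header_get <- function(key, required = TRUE) {
    i <- which(keys == key)[1]
    if (is.na(i)) {
      if (required) stop(sprintf("malformed header: missing '%s' in %s", key, path),
                         call. = FALSE)
      return(NA_character_)
    }
    vals[i]
  }
  header_get("File Rev")
  beam_id <- header_get("Beam ID")
  total_mu <- as.numeric(header_get("Total MU"))
  gantry <- as.numeric(header_get("Gantry"))
  n_cp <- as.integer(header_get("Number of Fields"))
  if (!is.finite(total_mu) || !is.finite(gantry) || is.na(n_cp)) {
    stop("malformed header: non-numeric Total MU / Gantry / Number of Fields",
         call. = FALSE)
  }
  cp_lines <- which(keys == "Index")
  if (length(cp_lines) != n_cp) {
    stop(sprintf("header announces %d control points but %d 'Index' blocks found",
                 n_cp, length(cp_lines)), call. = FALSE)
  }
  np <- geometry$n_pairs
  index <- numeric(n_cp)
  bank_a <- matrix(NA_real_, n_cp, np)
  bank_b <- matrix(NA_real_, n_cp, np)
  for (k in seq_len(n_cp)) {
    at <- cp_lines[k]
    index[k] <- as.numeric(vals[at])
    if (!is.finite(index[k]) || index[k] < -1e-9 || index[k] > 1 + 1e-9) {
      stop(sprintf("line %d: Index out of [0,1]", at), call. = FALSE)
    }
    if (k > 1 && index[k] < index[k - 1] - 1e-9) {
      stop(sprintf("line %d: non-monotone Index at control point %d", at, k),
           call. = FALSE)
    }
    for (bank in c("A", "B")) {
      for (p in seq_len(np)) {
        row <- at + (if (bank == "A") p else np + p)
        key_exp <- sprintf("Leaf %d%s", p, bank)
        if (row > length(keys) || is.na(keys[row]) || keys[row] != key_exp) {
          stop(sprintf("line %d: expected '%s'", row, key_exp), call. = FALSE)
        }
        pos_mm <- as.numeric(vals[row]) * 10   # file stores cm
        if (!is.finite(pos_mm)) {
          stop(sprintf("line %d: non-numeric position", row), call. = FALSE)
        }
        if (bank == "A") bank_a[k, p] <- pos_mm else bank_b[k, p] <- pos_mm
      }
    }
    coll <- which(bank_a[k, ] > bank_b[k, ] + 1e-6)
    if (length(coll)) {
      stop(sprintf("line %d: leaf collision (pair %d) at control point %d",
                   at, coll[1], k), call. = FALSE)
    }
  }
  dynamic_beam(beam_id, index, bank_a, bank_b, total_mu,
               gantry_angle = gantry, geometry = geometry)
}

#' Write a control-point MLC sequence ("dva") file
#'
#' Serialises a [dynamic_beam()] to the canonical dva dialect: positions in cm
#' with 3 decimals (0.01 mm resolution), meterset index with 5 decimals. The
#' writer is bit-stable: writing the result of [read_mlc_file()] reproduces a
#' canonical file byte-identically.
#'
#' @param beam a valid `dynamic_beam`.
#' @param path output path.
#' @param plan_id plan identifier written to the header.
#' @return `path`, invisibly.
#' @export
write_mlc_file <- function(beam, path, plan_id = "NA") {
  validate_dynamic_beam(beam)
  np <- beam$geometry$n_pairs
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("File Rev = G")
  wl("Plan ID = %s", plan_id)
  wl("Beam ID = %s", beam$beam_id)
  wl("Total MU = %s", format(beam$total_mu))
  wl("Gantry = %s", format(beam$gantry_angle))
  wl("Number of Fields = %d", length(beam$index))
  for (k in seq_along(beam$index)) {
    wl("Index = %.5f", beam$index[k])
    for (p in seq_len(np)) wl("Leaf %d%s = %.3f", p, "A", beam$bank_a[k, p] / 10)
    for (p in seq_len(np)) wl("Leaf %d%s = %.3f", p, "B", beam$bank_b[k, p] / 10)
  }
  invisible(path)
}
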