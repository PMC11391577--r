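#' Write a force-field table to structured text
#'
#' The format is sectioned key-value / whitespace-table text
#' (`[options]`, `[electrostatics]`, `[bead_types]`, `[pairs]`, `[bonds]`,
#' `[angles]`). Numbers are printed with 17 significant digits, so
#' write + read round-trips every field exactly.
#'
#' @param ff a `cg_forcefield`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_forcefield <- function(ff, path) {
  num <- function(x) sprintf("%.17g", x)
  ln <- c("# cgionfit force-field table v1", "[options]")
  for (k in c("cutoff", "bond_prefactor"))
    ln <- c(ln, paste(k, num(ff$options[[k]])))
  ln <- c(ln, paste("lj_shift", ff$options$lj_shift),
          paste("mixing_fallback", ff$options$mixing_fallback),
          "[electrostatics]",
          paste("relative_permittivity",
                num(ff$electrostatics$relative_permittivity)),
          paste("method", ff$electrostatics$method),
          paste("real_space_cutoff", num(ff$electrostatics$real_space_cutoff)),
          paste("accuracy_s", num(ff$electrostatics$accuracy_s)),
          "[bead_types]")
  bt <- ff$bead_types
  for (i in seq_len(nrow(bt)))
    ln <- c(ln, paste(bt$name[i], num(bt$mass[i]), num(bt$charge[i]),
                      bt$category[i], num(bt$waters_included[i])))
  ln <- c(ln, "[pairs]")
  p <- ff$pairs
  for (i in seq_len(nrow(p)))
    ln <- c(ln, paste(p$type_i[i], p$type_j[i], num(p$epsilon[i]),
                      num(p$sigma[i]), p$form[i]))
  ln <- c(ln, "[bonds]")
  b <- ff$bonds
  for (i in seq_len(nrow(b)))
    ln <- c(ln, paste(b$type_i[i], b$type_j[i], num(b$k[i]), num(b$r0[i])))
  ln <- c(ln, "[angles]")
  a <- ff$angles
  for (i in seq_len(nrow(a)))
    ln <- c(ln, paste(a$type_i[i], a$type_j[i], a$type_k[i], num(a$k[i]),
                      num(a$theta0[i]), a$corr[i]))
  writeLines(ln, path)
  invisible(path)
}

#' Read a force-field table written by [write_forcefield()]
#'
#' @param path input file path
#' @return a `cg_forcefield`
#' @export
read_forcefield <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nchar(ln) > 0 & !startsWith(ln, "#")]
  sec <- cumsum(startsWith(ln, "["))
  secname <- gsub("\\[|\\]", "", ln[startsWith(ln, "[")])
  get_sec <- function(nm) {
    i <- which(secname == nm)
    if (!length(i)) return(character())
    body <- ln[sec == i]
    body[!startsWith(body, "[")]
  }
  kv <- function(rows) {
    parts <- strsplit(rows, "\\s+")
    setNames(lapply(parts, function(p) paste(p[-1], collapse = " ")),
             vapply(parts, `[[`, "", 1))
  }
  opt <- kv(get_sec("options"))
  esl <- kv(get_sec("electrostatics"))
  bt_rows <- strsplit(get_sec("bead_types"), "\\s+")
  bt <- do.call(rbind, lapply(bt_rows, function(p)
    bead_type(p[1], as.numeric(p[2]), as.numeric(p[3]), p[4],
              as.numeric(p[5]))))
  p_rows <- strsplit(get_sec("pairs"), "\\s+")
  pairs <- do.call(rbind, lapply(p_rows, function(p)
    data.frame(type_i = p[1], type_j = p[2], epsilon = as.numeric(p[3]),
               sigma = as.numeric(p[4]), form = p[5])))
  b_rows <- strsplit(get_sec("bonds"), "\\s+")
  bonds <- if (length(b_rows))
    do.call(rbind, lapply(b_rows, function(p)
      data.frame(type_i = p[1], type_j = p[2], k = as.numeric(p[3]),
                 r0 = as.numeric(p[4])))) else empty_bonds()
  a_rows <- strsplit(get_sec("angles"), "\\s+")
  angles <- if (length(a_rows))
    do.call(rbind, lapply(a_rows, function(p)
      data.frame(type_i = p[1], type_j = p[2], type_k = p[3],
                 k = as.numeric(p[4]), theta0 = as.numeric(p[5]),
                 corr = as.logical(p[6])))) else empty_angles()
  cg_forcefield(
    bead_types = bt, pairs = pairs, bonds = bonds, angles = angles,
    electrostatics = list(
      relative_permittivity = as.numeric(esl$relative_permittivity),
      method = esl$method,
      real_space_cutoff = as.numeric(esl$real_space_cutoff),
      accuracy_s = as.numeric(esl$accuracy_s)),
    cutoff = as.numeric(opt$cutoff),
    lj_shift = as.logical(opt$lj_shift),
    bond_prefactor = as.numeric(opt$bond_prefactor),
    mixing_fallback = as.logical(opt$mixing_fallback))
}
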