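#' Chain model of CA (and Cys SG) coordinates
#'
#' A lightweight per-chain structure: sequential 1-based residue indices,
#' 3-letter residue codes, CA coordinates and, where present, the Cys SG
#' coordinate used for disulfide detection. Original author numbering is
#' retained as metadata.
#'
#' @param chain chain identifier (single string).
#' @param resid character vector of 3-letter residue codes.
#' @param ca n x 3 matrix of CA coordinates (Angstrom).
#' @param sg n x 3 matrix of SG coordinates, NA rows where absent.
#' @param orig_resno original residue numbering (defaults to sequential).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(chain, resid, ca, sg = NULL, orig_resno = NULL) {
  ca <- as.matrix(ca)
  n <- length(resid)
  if (n == 0L) stop("structure_model: empty model (no CA atoms)")
  if (nrow(ca) != n || ncol(ca) != 3L) stop("structure_model: 'ca' must be n x 3")
  if (!all(is.finite(ca))) stop("structure_model: non-finite CA coordinates")
  if (is.null(sg)) sg <- matrix(NA_real_, n, 3)
  if (is.null(orig_resno)) orig_resno <- seq_len(n)
  structure(list(chain = as.character(chain)[1], resno = seq_len(n),
                 resid = toupper(as.character(resid)), ca = unname(ca),
                 sg = unname(as.matrix(sg)),
                 orig_resno = as.integer(orig_resno)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: chain %s, %d residues, %d Cys with SG\n",
              x$chain, length(x$resno),
              sum(x$resid == "CYS" & is.finite(x$sg[, 1]))))
  invisible(x)
}

#' One-letter sequence of a structure model
#' @param model a [structure_model].
#' @return Single string of one-letter codes (X for unknown residues).
#' @export
model_sequence <- function(model) {
  paste(aa321(model$resid), collapse = "")
}

aa_three <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
              "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
aa_one <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")

aa321 <- function(three) {
  i <- match(toupper(three), aa_three)
  out <- aa_one[i]
  out[is.na(out)] <- "X"
  out
}

aa123 <- function(one) {
  i <- match(toupper(one), aa_one)
  out <- aa_three[i]
  out[is.na(out)] <- "UNK"
  out
}

#' Read chain models from PDB or mmCIF
#'
#' PDB files are parsed with bio3d; mmCIF files with a minimal
#' `atom_site` loop reader. Only CA atoms (plus Cys SG) are retained;
#' residues are renumbered sequentially per chain with the original
#' numbering kept in `orig_resno`.
#'
#' @param path a `.pdb` or `.cif`/`.mmcif` file.
#' @return Named list of [structure_model], one per chain.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  atoms <- if (ext %in% c("cif", "mmcif")) {
    read_cif_atoms(path)
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    data.frame(chain = ifelse(is.na(a$chain), "A", a$chain), elety = a$elety,
               resid = a$resid, resno = a$resno,
               x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  }
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("read_structure: empty model: no CA atoms found")
  sg <- atoms[atoms$elety == "SG", , drop = FALSE]
  models <- lapply(split(ca, ca$chain), function(cc) {
    cc <- cc[order(cc$resno), , drop = FALSE]
    sgm <- matrix(NA_real_, nrow(cc), 3)
    sgc <- sg[sg$chain == cc$chain[1], , drop = FALSE]
    i <- match(cc$resno, sgc$resno)
    hit <- which(!is.na(i))
    if (length(hit))
      sgm[hit, ] <- as.matrix(sgc[i[hit], c("x", "y", "z")])
    structure_model(cc$chain[1], cc$resid,
                    as.matrix(cc[, c("x", "y", "z")]),
                    sg = sgm, orig_resno = cc$resno)
  })
  models[order(names(models))]
}

read_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lt <- trimws(lines)
  tag_idx <- grep("^_atom_site\\.", lt)
  if (!length(tag_idx)) stop("read_structure: no _atom_site loop in mmCIF")
  tags <- sub("^_atom_site\\.", "", lt[tag_idx])
  body_start <- max(tag_idx) + 1L
  body <- character()
  for (i in body_start:length(lt)) {
    if (!nzchar(lt[i]) || startsWith(lt[i], "_") || startsWith(lt[i], "#") ||
        startsWith(lt[i], "loop_") || startsWith(lt[i], "data_")) break
    body <- c(body, lt[i])
  }
  if (!length(body)) stop("read_structure: empty _atom_site loop")
  rows <- do.call(rbind, strsplit(body, "\\s+"))
  colnames(rows) <- tags
  need <- c("label_atom_id", "label_comp_id", "auth_asym_id", "auth_seq_id",
            "Cartn_x", "Cartn_y", "Cartn_z")
  alt <- c(auth_asym_id = "label_asym_id", auth_seq_id = "label_seq_id")
  for (nm in names(alt))
    if (!(nm %in% tags) && alt[[nm]] %in% tags)
      colnames(rows)[colnames(rows) == alt[[nm]]] <- nm
  miss <- setdiff(need, colnames(rows))
  if (length(miss))
    stop("read_structure: mmCIF missing atom_site field(s): ",
         paste(miss, collapse = ", "))
  data.frame(chain = rows[, "auth_asym_id"],
             elety = gsub('"', "", rows[, "label_atom_id"]),
             resid = rows[, "label_comp_id"],
             resno = as.integer(rows[, "auth_seq_id"]),
             x = as.numeric(rows[, "Cartn_x"]),
             y = as.numeric(rows[, "Cartn_y"]),
             z = as.numeric(rows[, "Cartn_z"]), stringsAsFactors = FALSE)
}

#' Write a chain model to PDB or mmCIF
#'
#' Writes CA atoms (and SG atoms for Cys that carry one). `models` may be
#' a single [structure_model] or a list of them.
#'
#' @param models a [structure_model] or list of models.
#' @param path destination file; the extension selects the dialect
#'   (`.cif`/`.mmcif` for mmCIF, anything else PDB).
#' @return `path`, invisibly.
#' @export
write_structure <- function(models, path) {
  if (inherits(models, "structure_model")) models <- list(models)
  ext <- tolower(tools::file_ext(path))
  atoms <- do.call(rbind, lapply(models, function(m) {
    n <- length(m$resno)
    ca <- data.frame(elety = "CA", resid = m$resid, chain = m$chain,
                     resno = m$resno, x = m$ca[, 1], y = m$ca[, 2], z = m$ca[, 3])
    has_sg <- which(is.finite(m$sg[, 1]))
    if (length(has_sg)) {
      sg <- data.frame(elety = "SG", resid = m$resid[has_sg], chain = m$chain,
                       resno = m$resno[has_sg], x = m$sg[has_sg, 1],
                       y = m$sg[has_sg, 2], z = m$sg[has_sg, 3])
      ca <- rbind(ca, sg)
    }
    ca[order(ca$resno, ca$elety), ]
  }))
  if (ext %in% c("cif", "mmcif")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("data_model", "#", "loop_",
                 paste0("_atom_site.", c("group_PDB", "id", "label_atom_id",
                                         "label_comp_id", "auth_asym_id",
                                         "auth_seq_id", "Cartn_x", "Cartn_y",
                                         "Cartn_z"))), con)
    writeLines(sprintf("ATOM %d %s %s %s %d %.3f %.3f %.3f",
                       seq_len(nrow(atoms)), atoms$elety, atoms$resid,
                       atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z),
               con)
    writeLines("#", con)
  } else {
    el <- substr(atoms$elety, 1, 1)
    recs <- sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
                    seq_len(nrow(atoms)), atoms$elety, atoms$resid,
                    substr(atoms$chain, 1, 1), atoms$resno,
                    atoms$x, atoms$y, atoms$z, el)
    writeLines(c(recs, "END"), path)
  }
  invisible(path)
}
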