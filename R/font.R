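# 5x7 bitmap font (column bytes, bit 0 = top row) for image annotations
font5x7 <- local({
  tab <- list(
    "0" = c(0x3E, 0x51, 0x49, 0x45, 0x3E), "1" = c(0x00, 0x42, 0x7F, 0x40, 0x00),
    "2" = c(0x42, 0x61, 0x51, 0x49, 0x46), "3" = c(0x21, 0x41, 0x45, 0x4B, 0x31),
    "4" = c(0x18, 0x14, 0x12, 0x7F, 0x10), "5" = c(0x27, 0x45, 0x45, 0x45, 0x39),
    "6" = c(0x3C, 0x4A, 0x49, 0x49, 0x30), "7" = c(0x01, 0x71, 0x09, 0x05, 0x03),
    "8" = c(0x36, 0x49, 0x49, 0x49, 0x36), "9" = c(0x06, 0x49, 0x49, 0x29, 0x1E),
    "-" = c(0x08, 0x08, 0x08, 0x08, 0x08), "+" = c(0x08, 0x08, 0x3E, 0x08, 0x08),
    "." = c(0x00, 0x60, 0x60, 0x00, 0x00), " " = c(0x00, 0x00, 0x00, 0x00, 0x00),
    "A" = c(0x7E, 0x11, 0x11, 0x11, 0x7E), "B" = c(0x7F, 0x49, 0x49, 0x49, 0x36),
    "C" = c(0x3E, 0x41, 0x41, 0x41, 0x22), "D" = c(0x7F, 0x41, 0x41, 0x22, 0x1C),
    "E" = c(0x7F, 0x49, 0x49, 0x49, 0x41), "F" = c(0x7F, 0x09, 0x09, 0x09, 0x01),
    "G" = c(0x3E, 0x41, 0x49, 0x49, 0x7A), "H" = c(0x7F, 0x08, 0x08, 0x08, 0x7F),
    "I" = c(0x00, 0x41, 0x7F, 0x41, 0x00), "J" = c(0x20, 0x40, 0x41, 0x3F, 0x01),
    "K" = c(0x7F, 0x08, 0x14, 0x22, 0x41), "L" = c(0x7F, 0x40, 0x40, 0x40, 0x40),
    "M" = c(0x7F, 0x02, 0x0C, 0x02, 0x7F), "N" = c(0x7F, 0x04, 0x08, 0x10, 0x7F),
    "O" = c(0x3E, 0x41, 0x41, 0x41, 0x3E), "P" = c(0x7F, 0x09, 0x09, 0x09, 0x06),
    "Q" = c(0x3E, 0x41, 0x51, 0x21, 0x5E), "R" = c(0x7F, 0x09, 0x19, 0x29, 0x46),
    "S" = c(0x46, 0x49, 0x49, 0x49, 0x31), "T" = c(0x01, 0x01, 0x7F, 0x01, 0x01),
    "U" = c(0x3F, 0x40, 0x40, 0x40, 0x3F), "V" = c(0x1F, 0x20, 0x40, 0x20, 0x1F),
    "W" = c(0x3F, 0x40, 0x38, 0x40, 0x3F), "X" = c(0x63, 0x14, 0x08, 0x14, 0x63),
    "Y" = c(0x07, 0x08, 0x70, 0x08, 0x07), "Z" = c(0x61, 0x51, 0x49, 0x45, 0x43),
    "?" = c(0x02, 0x01, 0x51, 0x09, 0x06))
  tab
})

# draw text at pixel (x, y) = top-left of the first glyph; 2D overlay,
# ignores the z-buffer
draw_text <- function(cv, x, y, text, color, align = c("left", "right")) {
  align <- match.arg(align)
  text <- toupper(as.character(text))
  chars <- strsplit(text, "")[[1]]
  if (align == "right") x <- x - 6L * length(chars)
  for (ch in chars) {
    glyph <- font5x7[[ch]]
    if (is.null(glyph)) glyph <- font5x7[["?"]]
    for (colk in 1:5) {
      bits <- glyph[colk]
      for (rowk in 0:6) {
        if (bitwAnd(bits, bitwShiftL(1L, rowk)) != 0L) {
          px <- x + colk - 1L; py <- y + rowk
          if (px >= 1 && px <= cv$w && py >= 1 && py <= cv$h) {
            cv$R[py, px] <- color[1]
            cv$G[py, px] <- color[2]
            cv$B[py, px] <- color[3]
          }
        }
      }
    }
    x <- x + 6L
  }
  invisible()
}
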