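# Embedded 5x7 bitmap font (digits, A-Z, space). Lowercase letters render as
# uppercase; any other character falls back to a hollow box glyph. A bitmap
# font is used instead of system font rendering so annotation output is
# byte-identical across platforms.
.FONT5X7 <- list(
  "0" = c("01110","10001","10011","10101","11001","10001","01110"),
  "1" = c("00100","01100","00100","00100","00100","00100","01110"),
  "2" = c("01110","10001","00001","00010","00100","01000","11111"),
  "3" = c("11111","00010","00100","00010","00001","10001","01110"),
  "4" = c("00010","00110","01010","10010","11111","00010","00010"),
  "5" = c("11111","10000","11110","00001","00001","10001","01110"),
  "6" = c("00110","01000","10000","11110","10001","10001","01110"),
  "7" = c("11111","00001","00010","00100","01000","01000","01000"),
  "8" = c("01110","10001","10001","01110","10001","10001","01110"),
  "9" = c("01110","10001","10001","01111","00001","00010","01100"),
  "A" = c("01110","10001","10001","11111","10001","10001","10001"),
  "B" = c("11110","10001","10001","11110","10001","10001","11110"),
  "C" = c("01110","10001","10000","10000","10000","10001","01110"),
  "D" = c("11100","10010","10001","10001","10001","10010","11100"),
  "E" = c("11111","10000","10000","11110","10000","10000","11111"),
  "F" = c("11111","10000","10000","11110","10000","10000","10000"),
  "G" = c("01110","10001","10000","10111","10001","10001","01111"),
  "H" = c("10001","10001","10001","11111","10001","10001","10001"),
  "I" = c("01110","00100","00100","00100","00100","00100","01110"),
  "J" = c("00111","00010","00010","00010","00010","10010","01100"),
  "K" = c("10001","10010","10100","11000","10100","10010","10001"),
  "L" = c("10000","10000","10000","10000","10000","10000","11111"),
  "M" = c("10001","11011","10101","10101","10001","10001","10001"),
  "N" = c("10001","10001","11001","10101","10011","10001","10001"),
  "O" = c("01110","10001","10001","10001","10001","10001","01110"),
  "P" = c("11110","10001","10001","11110","10000","10000","10000"),
  "Q" = c("01110","10001","10001","10001","10101","10010","01101"),
  "R" = c("11110","10001","10001","11110","10100","10010","10001"),
  "S" = c("01111","10000","10000","01110","00001","00001","11110"),
  "T" = c("11111","00100","00100","00100","00100","00100","00100"),
  "U" = c("10001","10001","10001","10001","10001","10001","01110"),
  "V" = c("10001","10001","10001","10001","10001","01010","00100"),
  "W" = c("10001","10001","10001","10101","10101","10101","01010"),
  "X" = c("10001","10001","01010","00100","01010","10001","10001"),
  "Y" = c("10001","10001","10001","01010","00100","00100","00100"),
  "Z" = c("11111","00001","00010","00100","01000","10000","11111"),
  " " = c("00000","00000","00000","00000","00000","00000","00000"),
  ".box" = c("11111","10001","10001","10001","10001","10001","11111")
)

# glyph as a 7x5 logical matrix; unsupported characters warn and fall back
# to the hollow box
.glyph_matrix <- function(ch) {
  key <- toupper(ch)
  rows <- .FONT5X7[[key]]
  if (is.null(rows)) {
    warning("unsupported character '", ch, "' replaced by box glyph",
            call. = FALSE)
    rows <- .FONT5X7[[".box"]]
  }
  do.call(rbind, lapply(rows, function(r) {
    as.integer(strsplit(r, "")[[1]]) == 1L
  }))
}

# pixel count of one glyph, used by tests as the drawing oracle
.glyph_pixel_count <- function(ch) sum(.glyph_matrix(ch))
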