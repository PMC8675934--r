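# Column schema of a community table CSV (wide layout, RFC 4180, UTF-8).
# Identifier columns, 13 soil variables measured once per subplot,
# year-level annual precipitation (mm), and one integer abundance column
# per species (four-letter codes).
id:
  - "plot"
  - "subplot"
  - "year"
  - "x"
  - "y"
abiotic:
  - "pH"
  - "salinity"
  - "carbonates"
  - "organic_matter"
  - "cn_ratio"
  - "Cl"
  - "C"
  - "N"
  - "P"
  - "Ca"
  - "Mg"
  - "K"
  - "Na"
  - "precipitation"
species:
  - "ANAR"
  - "BEMA"
  - "CETE"
  - "CHFU"
  - "CHMI"
  - "COSQ"
  - "FRPU"
  - "HOMA"
  - "LEMA"
  - "LYTR"
  - "MEEL"
  - "MEPO"
  - "MESU"
  - "PAIN"
  - "PLCO"
  - "POMA"
  - "POMO"
  - "PUPA"
  - "SASO"
  - "SCLA"
  - "SOAS"
  - "SPRU"
  - "SUSP"
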