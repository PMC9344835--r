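Package: cdmsteward
Title: Clinical Data Model Management and Semantic Harmonization of Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and maintaining a clinical data model (CDM):
    a catalog of standardized study variables with definitions, data types,
    value ranges, modalities and ontology cross-references. Study datasets
    are mapped onto the CDM by fuzzy string matching of column names (with
    offline ontology-term autosuggestion), coerced and validated against the
    variable metadata, and stored as harmonized entity-attribute-value
    records that can be queried and exported to SKOS/RDF (Turtle and
    RDF/XML), HL7 FHIR R4 bundles and OMOP-aligned tables. A seeded
    generator of dementia-cohort-like virtual patients provides
    reproducible demonstration and test data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    igraph,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
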