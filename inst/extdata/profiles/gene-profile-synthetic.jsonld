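{
  "@context": {
    "schema": "https://schema.org/",
    "profiles": "https://bioschemas.org/terms/"
  },
  "@id": "https://bioschemas.org/profiles/Gene/1.0-RELEASE",
  "@type": "profiles:Profile",
  "name": "Gene",
  "description": "Synthetic in-package fixture copy of the community Gene profile: a web page describing a gene should at minimum provide an identifier and a name, and is recommended to also provide a description and a reference web page.",
  "targetClass": "schema:Gene",
  "properties": [
    { "property": "schema:identifier", "marginality": "Minimum" },
    { "property": "schema:name", "marginality": "Minimum" },
    { "property": "schema:description", "marginality": "Recommended" },
    { "property": "schema:url", "marginality": "Recommended" },
    { "property": "schema:alternateName", "marginality": "Optional" }
  ]
}
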