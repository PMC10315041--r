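{
  "@context": {
    "schema": "https://schema.org/",
    "profiles": "https://bioschemas.org/terms/"
  },
  "@id": "https://bioschemas.org/profiles/ComputationalTool/1.0-RELEASE",
  "@type": "profiles:Profile",
  "name": "ComputationalTool",
  "description": "Synthetic in-package fixture copy of the community ComputationalTool profile for software applications: name, description and a landing page are the minimum; software-specific descriptors are recommended.",
  "targetClass": "schema:SoftwareApplication",
  "properties": [
    { "property": "schema:name", "marginality": "Minimum" },
    { "property": "schema:description", "marginality": "Minimum" },
    { "property": "schema:url", "marginality": "Minimum" },
    { "property": "schema:additionalType", "marginality": "Recommended" },
    { "property": "schema:applicationCategory", "marginality": "Recommended" },
    { "property": "schema:applicationSubCategory", "marginality": "Recommended" },
    { "property": "schema:citation", "marginality": "Recommended" },
    { "property": "schema:featureList", "marginality": "Recommended" },
    { "property": "schema:operatingSystem", "marginality": "Recommended" },
    { "property": "schema:softwareVersion", "marginality": "Recommended" },
    { "property": "schema:softwareHelp", "marginality": "Optional" }
  ]
}
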