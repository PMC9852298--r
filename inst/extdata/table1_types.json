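{
  "types": ["a1", "a2", "a3"],
  "neutral": ["a1"],
  "opposing": [
    ["a2", "a3"]
  ],
  "agents": ["i", "j"],
  "events": ["e001", "e002", "e003", "e004", "e005", "e006", "e007", "e008", "e009", "e010", "e011", "e012", "e013", "e014", "e015", "e016", "e017", "e018", "e019", "e020", "e021", "e022", "e023", "e024", "e025", "e026", "e027", "e028", "e029", "e030", "e031", "e032", "e033", "e034", "e035", "e036", "e037", "e038", "e039", "e040", "e041", "e042", "e043", "e044", "e045", "e046", "e047", "e048", "e049", "e050", "e051", "e052", "e053", "e054", "e055", "e056", "e057", "e058", "e059", "e060", "e061", "e062", "e063", "e064", "e065", "e066", "e067", "e068", "e069", "e070", "e071", "e072", "e073", "e074", "e075", "e076", "e077", "e078", "e079", "e080", "e081", "e082", "e083", "e084", "e085", "e086", "e087", "e088", "e089", "e090", "e091", "e092", "e093", "e094", "e095", "e096", "e097", "e098", "e099", "e100"]
}
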