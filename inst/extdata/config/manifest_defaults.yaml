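# Default NBIA Retriever manifest header values. The historical key spelling
# "noOfrRetry" is preserved for bit-compatibility with the consuming tool.
server_url: "https://public.cancerimagingarchive.net/nbia-download/servlet/DownloadServlet"
include_annotation: true
retries: 4
basket_id: "manifest-omopmri.tcia"
manifest_version: "3.0"
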