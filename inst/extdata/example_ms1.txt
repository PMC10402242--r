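# nativeTDP peaklist v1
BEGIN SPECTRUM id=ms1
ms_level=1
473.464401 100.000000
525.959637 80.000000
END SPECTRUM
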