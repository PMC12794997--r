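raw	canonical
chantix	VARENICLINE
brand-varenicline	VARENICLINE
accutane	ISOTRETINOIN
brand-isotretinoin	ISOTRETINOIN
humira	ADALIMUMAB
brand-adalimumab	ADALIMUMAB
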