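raw	final
http://bit.ly/vapedeal	http://vaporgod.example.com/shop
http://bit.ly/ecigkit	http://ecigarettesstarterkits.example.com/free-kit
http://t.co/blusale	http://blu.example.com/sale
http://tinyurl.com/sbsmoke	http://southbeachsmoke.example.com
http://ow.ly/v2promo	http://v2cigs.example.com/promo
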