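https://t.co/m0001	https://cannabiswire.example.com/news/legalization-vote
https://t.co/m0002	https://drugnewsdaily.example.org/report/edibles-policy
https://t.co/r0001	https://budshop420.example.com/shop/vape-cartridge-sale
https://t.co/r0002	https://greenleafstore.example.net/buy/k2-spice-stock
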