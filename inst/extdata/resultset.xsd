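<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema for serialized query result sets: ordered column declarations,
     then rows carrying one provenance uid each and one cell per column.
     An empty cell is an absent value. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:element name="resultset">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="columns">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="column" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="name" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="rows">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="row" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="cell" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:choice minOccurs="0">
                          <xs:element name="number">
                            <xs:complexType>
                              <xs:attribute name="v" type="xs:double" use="required"/>
                            </xs:complexType>
                          </xs:element>
                          <xs:element name="string">
                            <xs:complexType>
                              <xs:attribute name="v" type="xs:string" use="required"/>
                            </xs:complexType>
                          </xs:element>
                          <xs:element name="quantity">
                            <xs:complexType>
                              <xs:attribute name="magnitude" type="xs:double" use="required"/>
                              <xs:attribute name="units" type="xs:string" use="required"/>
                            </xs:complexType>
                          </xs:element>
                          <xs:element name="coded_text">
                            <xs:complexType>
                              <xs:attribute name="code" type="xs:string" use="required"/>
                              <xs:attribute name="terminology" type="xs:string" use="required"/>
                              <xs:attribute name="label" type="xs:string" use="required"/>
                            </xs:complexType>
                          </xs:element>
                          <xs:element name="text">
                            <xs:complexType>
                              <xs:attribute name="v" type="xs:string" use="required"/>
                            </xs:complexType>
                          </xs:element>
                          <xs:element name="timestamp">
                            <xs:complexType>
                              <xs:attribute name="v" type="xs:string" use="required"/>
                            </xs:complexType>
                          </xs:element>
                        </xs:choice>
                        <xs:attribute name="column" type="xs:string" use="required"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                  <xs:attribute name="uid" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
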